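# Single-threaded BLAS: the dense kernels here are small (n ~ 150), where
# thread fan-out costs more than it saves.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
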