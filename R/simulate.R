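#' Configuration for the synthetic cohort generator
#'
#' Defines the known structure-function-time model the generator draws
#' from. Each patient receives a smooth ellipsoidal abnormality lesion
#' placed in a toy ellipsoidal brain (with a configurable left-hemisphere
#' bias), the lesion is pushed through the real pipeline (binarization,
#' atlas encoding) to obtain damage proportions `d_r` and volume `V`, and a
#' latent impairment
#' \deqn{I = \sum_r w_r d_r + w_V \cdot V / |brain|}
#' drives the composite score at `t` months post-stroke via a saturating
#' recovery model
#' \deqn{score(t) = \theta - I\,(\rho + (1 - \rho)\, e^{-t/\tau}) + u +
#'   \epsilon, \quad u \sim N(0, \sigma_u^2),\;
#'   \epsilon \sim N(0, \sigma^2).}
#' `rho` is the residual (never-recovering) fraction of the initial
#' impairment, `tau` the recovery time constant in months, and `theta` the
#' ceiling score of an unimpaired patient. `u` is a stable per-patient
#' effect shared across visits — the individual variability that lesion
#' features cannot explain but a patient's own earlier assessment reveals,
#' which is what makes longitudinal prediction more accurate than
#' cross-sectional prediction. Demographics are drawn independently of
#' outcome, so demographics-only models should explain essentially no
#' variance.
#'
#' @param n_patients Number of patients. Default 150.
#' @param grid Grid shape in voxels. Default `c(40, 48, 40)`.
#' @param voxel_size Isotropic voxel size in mm. Default 2.
#' @param n_regions Parcellation regions in the toy atlas. Default 20.
#' @param n_informative Number of regions with non-zero weight. Default 3.
#' @param informative_weights T-score impairment per unit damage proportion
#'   for each informative region. Default `c(35, 30, 25)`.
#' @param volume_weight T-score impairment per unit lesioned brain fraction.
#'   Default 20.
#' @param ceiling Unimpaired score theta (T). Default 70.
#' @param rho Residual impairment fraction in `[0, 1]`. Default 0.5.
#' @param tau Recovery time constant (months). Default 6.
#' @param noise_sd Observation noise SD sigma (T units). Default 3.
#' @param patient_sd SD of a stable per-patient effect (T units), drawn once
#'   per patient and shared by all of their visits: the individual factors
#'   (premorbid ability, therapy, education) that lesion features cannot
#'   explain but an earlier assessment reveals. Default 4.
#' @param task_offset_sd SD of the small per-task offsets added to the
#'   latent score to form the four task T-scores. Default 0.5.
#' @param repeat_prob Probability a patient has a second assessment.
#'   Default 0.15.
#' @param repeat_gap Range (months) of the uniform gap to the repeat visit.
#'   Default `c(6, 24)`.
#' @param left_bias Probability a lesion is placed in the left hemisphere.
#'   Default 0.8.
#' @param time_meanlog,time_sdlog Log-normal parameters of first-visit time
#'   post-stroke (months), clipped to `[1, 240]`. Defaults `log(12)`, 0.8.
#' @param flag_prob Probability of each human-judged exclusion flag being
#'   set. Default 0.
#' @param threshold,min_cluster Binarization parameters used by the
#'   generator's own pipeline pass (defaults 0.3, 100).
#' @param seed Master seed; the whole cohort is a deterministic function of
#'   it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 150, grid = c(40, 48, 40),
                       voxel_size = 2, n_regions = 20, n_informative = 3,
                       informative_weights = c(35, 30, 25),
                       volume_weight = 20, ceiling = 70, rho = 0.5,
                       tau = 6, noise_sd = 3, patient_sd = 4,
                       task_offset_sd = 0.5,
                       repeat_prob = 0.15, repeat_gap = c(6, 24),
                       left_bias = 0.8, time_meanlog = log(12),
                       time_sdlog = 0.8, flag_prob = 0, threshold = 0.3,
                       min_cluster = 100, seed = 1) {
  stopifnot(length(grid) == 3, n_regions >= 2,
            n_informative <= n_regions,
            length(informative_weights) == n_informative,
            all(is.finite(informative_weights)),
            noise_sd >= 0, patient_sd >= 0, rho >= 0, rho <= 1, tau > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Ellipsoidal toy brain mask and its MNI-like affine (origin at the grid
# center, so world x < 0 is the left hemisphere).
toy_brain <- function(cfg) {
  dims <- cfg$grid
  affine <- diag(c(rep(cfg$voxel_size, 3), 1))
  affine[1:3, 4] <- -cfg$voxel_size * floor(dims / 2)
  semi <- 0.45 * dims
  ctr <- (dims + 1) / 2
  d2 <- outer(outer(((seq_len(dims[1]) - ctr[1]) / semi[1])^2,
                    ((seq_len(dims[2]) - ctr[2]) / semi[2])^2, `+`),
              ((seq_len(dims[3]) - ctr[3]) / semi[3])^2, `+`)
  list(mask = d2 <= 1, affine = affine, dims = dims)
}

# Voronoi-style parcellation of the brain mask: k-means on voxel
# coordinates gives n_regions compact contiguous regions.
toy_parcellation <- function(brain, n_regions) {
  idx <- which(brain$mask, arr.ind = TRUE)
  # Hartigan-Wong may hit its Quick-TRANSfer cap on tens of thousands of
  # voxels; the partition is still a perfectly usable Voronoi atlas.
  km <- suppressWarnings(kmeans(idx, centers = n_regions, iter.max = 50,
                                nstart = 1))
  labels <- array(0L, dim = brain$dims)
  labels[brain$mask] <- km$cluster
  wx <- brain$affine[1, 1] * (km$centers[, 1] - 1) + brain$affine[1, 4]
  hemi <- ifelse(wx < -1e-8, "L", ifelse(wx > 1e-8, "R", "M"))
  regions <- data.frame(region_id = seq_len(n_regions),
                        name = sprintf("region_%02d", seq_len(n_regions)),
                        hemisphere = hemi, stringsAsFactors = FALSE)
  parcellation(labels, regions, affine = brain$affine)
}

# One smooth ellipsoidal abnormality bump inside the brain, guaranteed to
# survive binarization with >= min_cluster voxels. Retries with fresh
# geometry; fails loudly if the grid cannot host a lesion.
place_lesion <- function(brain, hemi_left, cfg, max_tries = 25) {
  dims <- brain$dims
  wx_axis <- brain$affine[1, 1] * (seq_len(dims[1]) - 1) + brain$affine[1, 4]
  side_ok <- if (hemi_left) wx_axis < 0 else wx_axis > 0
  cand <- which(brain$mask & array(side_ok, dim = dims), arr.ind = TRUE)
  for (try in seq_len(max_tries)) {
    ctr <- cand[sample.int(nrow(cand), 1), ]
    radii <- runif(3, 3.5, 10)
    peak <- runif(1, 0.5, 1)
    m2 <- outer(outer(((seq_len(dims[1]) - ctr[1]) / radii[1])^2,
                      ((seq_len(dims[2]) - ctr[2]) / radii[2])^2, `+`),
                ((seq_len(dims[3]) - ctr[3]) / radii[3])^2, `+`)
    vals <- peak * exp(-0.5 * m2)
    vals[!brain$mask] <- 0
    vals[vals < 1e-3] <- 0
    img <- abnormality_image(vals, affine = brain$affine)
    mask <- binarize_lesion(img, threshold = cfg$threshold,
                            min_cluster = cfg$min_cluster)
    if (mask$n_voxels >= cfg$min_cluster)
      return(list(image = img, mask = mask))
  }
  stop("could not place a lesion of >= ", cfg$min_cluster,
       " voxels inside the brain mask after ", max_tries, " attempts")
}

#' Simulate a complete synthetic cohort
#'
#' Generates toy brain + parcellation, per-patient abnormality images,
#' demographics, times post-stroke, per-task T-scores and repeat visits
#' from the known generative model in [sim_config()]. Lesion features in
#' the returned records are computed by the package's own pipeline
#' ([binarize_lesion()], [atlas_proportions()]), so every downstream stage
#' is exercised end to end. The cohort is a deterministic function of
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort` with `records` (patient table: ids,
#'   visit index, demographics, time post-stroke, four task T-scores,
#'   `speech_score` composite, exclusion flags, lesion volume features and
#'   `dmg_*` damage proportions), `images` (named list of
#'   [abnormality_image()]s), `masks`, `parcellation`, `truth` (informative
#'   regions, weights, per-patient latent impairment, per-record noise-free
#'   scores) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    brain <- toy_brain(cfg)
    parc <- toy_parcellation(brain, cfg$n_regions)
    left_ids <- parc$regions$region_id[parc$regions$hemisphere == "L"]
    pool <- if (length(left_ids) >= cfg$n_informative) left_ids
      else parc$regions$region_id
    informative <- sort(sample(pool, cfg$n_informative))
    weights <- cfg$informative_weights
    names(weights) <- parc$regions$name[match(informative,
                                              parc$regions$region_id)]
    brain_voxels <- sum(brain$mask)

    ids <- sprintf("P%03d", seq_len(cfg$n_patients))
    images <- masks <- vector("list", cfg$n_patients)
    names(images) <- names(masks) <- ids
    rows <- vector("list", 2L * max(cfg$n_patients, 1L))
    truth_rows <- vector("list", 2L * max(cfg$n_patients, 1L))
    impairment <- numeric(cfg$n_patients)
    names(impairment) <- ids
    k <- 0L

    score_at <- function(I, t) {
      cfg$ceiling - I * (cfg$rho + (1 - cfg$rho) * exp(-t / cfg$tau))
    }

    for (i in seq_len(cfg$n_patients)) {
      hemi_left <- runif(1) < cfg$left_bias
      les <- place_lesion(brain, hemi_left, cfg)
      images[[i]] <- les$image
      masks[[i]] <- les$mask
      dmg <- atlas_proportions(les$mask, parc)
      vol <- lesion_volume(les$mask)
      latv <- lateralised_volumes(les$mask)
      I <- sum(weights * dmg[names(weights)]) +
        cfg$volume_weight * vol / brain_voxels
      impairment[i] <- I

      u <- rnorm(1, 0, cfg$patient_sd)   # stable per-patient effect
      age <- round(runif(1, 25, 85))
      gender <- rbinom(1, 1, 0.35)
      handed <- rbinom(1, 1, 0.9)
      flags <- runif(3) < cfg$flag_prob
      n_vis <- 1L + (runif(1) < cfg$repeat_prob)
      t_vis <- min(max(rlnorm(1, cfg$time_meanlog, cfg$time_sdlog), 1), 240)
      for (v in seq_len(n_vis)) {
        if (v > 1L)
          t_vis <- min(t_vis + runif(1, cfg$repeat_gap[1], cfg$repeat_gap[2]),
                       240)
        latent <- score_at(I, t_vis) + u
        eps <- rnorm(1, 0, cfg$noise_sd)
        tasks <- latent + eps + rnorm(4, 0, cfg$task_offset_sd)
        names(tasks) <- c("t_word_rep", "t_sent_rep", "t_naming", "t_pic_desc")
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient_id = ids[i], visit_index = v, age_at_stroke = age,
          gender = gender, handedness = handed, time_post_stroke = t_vis,
          t_word_rep = tasks[1], t_sent_rep = tasks[2],
          t_naming = tasks[3], t_pic_desc = tasks[4],
          flag_neuro = flags[1], flag_language = flags[2],
          flag_no_damage = flags[3],
          lesion_volume = vol, left_volume = latv[["left"]],
          right_volume = latv[["right"]], stringsAsFactors = FALSE)
        truth_rows[[k]] <- data.frame(
          patient_id = ids[i], visit_index = v, impairment = I,
          patient_effect = u, latent_score = latent, noise = eps,
          stringsAsFactors = FALSE)
      }
      rows[[k]] <- cbind(rows[[k]],
                         as.data.frame(as.list(setNames(dmg,
                           paste0("dmg_", names(dmg))))))
      if (n_vis > 1L)
        rows[[k - 1L]] <- cbind(rows[[k - 1L]],
                                as.data.frame(as.list(setNames(dmg,
                                  paste0("dmg_", names(dmg))))))
    }
    records <- do.call(rbind, rows[seq_len(k)])
    if (k > 0) {
      records$speech_score <- composite_speech_score(records)
      records <- records[order(records$patient_id, records$visit_index), ]
      rownames(records) <- NULL
    } else {
      records <- empty_records(parc)
    }
    truth <- list(informative_regions = names(weights),
                  weights = weights,
                  volume_weight = cfg$volume_weight,
                  brain_voxels = brain_voxels,
                  ceiling = cfg$ceiling, rho = cfg$rho, tau = cfg$tau,
                  noise_sd = cfg$noise_sd,
                  impairment = impairment,
                  records = do.call(rbind, truth_rows[seq_len(k)]))
    structure(list(records = records, images = images, masks = masks,
                   parcellation = parc, brain = brain, truth = truth,
                   config = cfg),
              class = "sim_cohort")
  })
}

empty_records <- function(parc) {
  base <- data.frame(patient_id = character(), visit_index = integer(),
                     age_at_stroke = numeric(), gender = integer(),
                     handedness = integer(), time_post_stroke = numeric(),
                     t_word_rep = numeric(), t_sent_rep = numeric(),
                     t_naming = numeric(), t_pic_desc = numeric(),
                     flag_neuro = logical(), flag_language = logical(),
                     flag_no_damage = logical(), lesion_volume = integer(),
                     left_volume = integer(), right_volume = integer(),
                     stringsAsFactors = FALSE)
  for (nm in paste0("dmg_", parc$regions$name)) base[[nm]] <- numeric()
  base$speech_score <- numeric()
  base
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d records, %d regions, seed %d\n",
              x$config$n_patients, nrow(x$records),
              nrow(x$parcellation$regions), x$config$seed))
  invisible(x)
}

#' First-visit / repeat-visit split of a cohort's records
#'
#' @param records A cohort's patient table.
#' @return List with `first` (visit_index 1) and `repeats` (later visits).
#' @export
split_visits <- function(records) {
  list(first = records[records$visit_index == 1L, , drop = FALSE],
       repeats = records[records$visit_index > 1L, , drop = FALSE])
}

#' Write a synthetic cohort to disk as plain fixtures
#'
#' Writes per-patient abnormality NIfTIs, the atlas label image + region
#' CSV, the patient table CSV (full double precision, so read-back is
#' exact), the ground truth JSON and a `manifest.csv` of MD5 checksums.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.csv`.
#' @export
write_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  paths <- character()
  for (id in names(cohort$images)) {
    p <- file.path(out_dir, "images", paste0(id, ".nii.gz"))
    write_nifti_volume(cohort$images[[id]]$grid, cohort$images[[id]]$affine,
                       p, datatype = "double")
    paths <- c(paths, p)
  }
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_nifti_volume(cohort$parcellation$labels, cohort$parcellation$affine,
                     atlas_path, datatype = "int")
  regions_path <- file.path(out_dir, "regions.csv")
  write.csv(cohort$parcellation$regions[c("region_id", "name", "hemisphere")],
            regions_path, row.names = FALSE)
  patients_path <- file.path(out_dir, "patients.csv")
  write_exact_csv(cohort$records, patients_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(informative_regions = cohort$truth$informative_regions,
         weights = as.list(cohort$truth$weights),
         volume_weight = cohort$truth$volume_weight,
         brain_voxels = cohort$truth$brain_voxels,
         ceiling = cohort$truth$ceiling, rho = cohort$truth$rho,
         tau = cohort$truth$tau, noise_sd = cohort$truth$noise_sd,
         impairment = as.list(cohort$truth$impairment),
         records = cohort$truth$records),
    truth_path, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, atlas_path, regions_path, patients_path, truth_path)
  rel <- substring(paths, nchar(file.path(out_dir, "")) + 1L)
  manifest <- data.frame(file = rel,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# CSV with doubles rendered at 17 significant digits: numeric round trips
# through read.csv are bit-exact.
write_exact_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a cohort written by [write_fixtures()]
#'
#' @param dir Fixture directory.
#' @return List with `records`, `images`, `parcellation`, `truth`,
#'   `manifest`.
#' @export
read_cohort <- function(dir) {
  records <- read.csv(file.path(dir, "patients.csv"),
                      stringsAsFactors = FALSE)
  parc <- load_parcellation(file.path(dir, "atlas.nii.gz"),
                            file.path(dir, "regions.csv"))
  image_files <- sort(list.files(file.path(dir, "images"),
                                 full.names = TRUE))
  images <- lapply(image_files, read_abnormality_image)
  names(images) <- sub("\\.nii(\\.gz)?$", "", basename(image_files))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  list(records = records, images = images, parcellation = parc,
       truth = truth, manifest = manifest)
}
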