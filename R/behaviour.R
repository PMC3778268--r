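#' Composite speech-production score
#'
#' Builds the composite outcome from four per-task T-scores: word repetition
#' and sentence repetition (aural stimuli), object naming and picture
#' description (visual stimuli). Each task is first aligned so that its
#' impairment threshold equals `reference` (adding
#' `reference - threshold[task]` to its scores); the composite is then the
#' mean of the minimum aligned score within the visual pair and the minimum
#' within the aural pair, tracking impairment that cuts across the two
#' stimulus modalities. On the aligned scale, "impaired" means a composite
#' below `reference` (default 60, the bottom 5% of neurologically normal
#' controls).
#'
#' @param scores Named numeric vector, or data frame of per-patient rows,
#'   with elements/columns `t_word_rep`, `t_sent_rep`, `t_naming`,
#'   `t_pic_desc`.
#' @param thresholds Named numeric vector of per-task impairment thresholds
#'   (same names). These come from control norms and are supplied as inputs;
#'   the default sets all four to `reference` so alignment constants are 0.
#' @param reference Common threshold the tasks are aligned to. Default 60.
#' @return Numeric vector of composite T-scores (length 1 for a vector
#'   input, `nrow(scores)` for a data frame).
#' @export
composite_speech_score <- function(scores,
                                   thresholds = c(t_word_rep = 60, t_sent_rep = 60,
                                                  t_naming = 60, t_pic_desc = 60),
                                   reference = 60) {
  tasks <- c("t_word_rep", "t_sent_rep", "t_naming", "t_pic_desc")
  if (!all(tasks %in% names(thresholds)))
    stop("`thresholds` must name all four tasks: ", paste(tasks, collapse = ", "))
  if (is.data.frame(scores)) {
    if (!all(tasks %in% names(scores)))
      stop("missing task score column(s): ",
           paste(setdiff(tasks, names(scores)), collapse = ", "))
    s <- as.matrix(scores[tasks])
  } else {
    if (!all(tasks %in% names(scores)))
      stop("missing task score(s): ",
           paste(setdiff(tasks, names(scores)), collapse = ", "))
    s <- matrix(scores[tasks], nrow = 1, dimnames = list(NULL, tasks))
  }
  if (any(!is.finite(s)))
    stop("task T-scores must all be present and finite")
  aligned <- sweep(s, 2, reference - thresholds[tasks], `+`)
  aural <- pmin(aligned[, "t_word_rep"], aligned[, "t_sent_rep"])
  visual <- pmin(aligned[, "t_naming"], aligned[, "t_pic_desc"])
  unname((visual + aural) / 2)
}

#' Apply the cohort selection criteria
#'
#' Filters patient records with the standard exclusion rules: (a) age at
#' stroke strictly below 20 or above 90 years; (b) assessed less than
#' 1 month post-stroke; (c--e) human-judged flags (other neurological
#' conditions, non-native language, no visible damage); (f) no focal lesion
#' surviving the binarization cluster filter (empty mask). Boundary ages 20
#' and 90 are kept. Each excluded record gets one reason code, the first
#' triggered in (a)--(f) order. The filter is pure: order-independent and
#' idempotent.
#'
#' @param records Data frame with columns `patient_id`, `age_at_stroke`,
#'   `time_post_stroke` (months), logical flags `flag_neuro`,
#'   `flag_language`, `flag_no_damage`, and (unless `masks` is supplied)
#'   `lesion_volume` in voxels.
#' @param masks Optional named list of `binary_lesion` objects, one per
#'   patient id; when given, lesion emptiness is taken from the masks
#'   instead of the `lesion_volume` column.
#' @param min_age,max_age,min_months Selection bounds (inclusive), defaults
#'   20, 90 and 1.
#' @return List with `kept` (the retained records) and `log` (data frame
#'   `patient_id`, `visit_index`, `reason` for every excluded record; reasons
#'   are `"age"`, `"time"`, `"neurological"`, `"language"`,
#'   `"no_visible_damage"`, `"lesion_size"`).
#' @export
apply_selection_criteria <- function(records, masks = NULL,
                                     min_age = 20, max_age = 90,
                                     min_months = 1) {
  records <- as.data.frame(records)
  vol <- if (!is.null(masks)) {
    vapply(as.character(records$patient_id),
           function(id) lesion_volume(masks[[id]]), numeric(1))
  } else records$lesion_volume
  flag <- function(col) if (col %in% names(records)) isTRUE_vec(records[[col]])
    else rep(FALSE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  hit <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- hit(records$age_at_stroke < min_age | records$age_at_stroke > max_age, "age")
  reason <- hit(records$time_post_stroke < min_months, "time")
  reason <- hit(flag("flag_neuro"), "neurological")
  reason <- hit(flag("flag_language"), "language")
  reason <- hit(flag("flag_no_damage"), "no_visible_damage")
  reason <- hit(vol == 0, "lesion_size")
  excluded <- !is.na(reason)
  log <- data.frame(patient_id = records$patient_id[excluded],
                    visit_index = if ("visit_index" %in% names(records))
                      records$visit_index[excluded] else 1L,
                    reason = reason[excluded],
                    stringsAsFactors = FALSE)
  list(kept = records[!excluded, , drop = FALSE], log = log)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
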