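# Predictor configurations.
#
# The configuration ladder mirrors how lesion information is progressively
# introduced: demographics only; plus total lesion volume; plus lateralised
# (left/right) volumes; plus per-region atlas damage proportions; and
# finally the ARD-selected subset of the atlas pool.

DEM_COLUMNS <- c("time_post_stroke", "age_at_stroke", "gender", "handedness")

#' Damage-feature column names of a patient table
#'
#' Atlas damage proportions live in columns prefixed `dmg_`, one per region,
#' in the parcellation's region order.
#'
#' @param records Patient data frame.
#' @return Character vector of damage column names.
#' @export
damage_columns <- function(records) {
  grep("^dmg_", names(records), value = TRUE)
}

#' Resolve a predictor configuration to column names
#'
#' @param records Patient data frame.
#' @param config One of `"dem"` (time post-stroke, age at stroke, gender,
#'   handedness), `"dem_lv"` (+ total lesion volume), `"dem_latv"`
#'   (+ left/right lesion volumes), `"atlas"` (demographics + lesion volume +
#'   all `dmg_` regional damage proportions), or an explicit character vector
#'   of column names (e.g. an ARD-selected subset).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(records, config = "atlas") {
  if (length(config) > 1 || !config %in% c("dem", "dem_lv", "dem_latv", "atlas")) {
    missing <- setdiff(config, names(records))
    if (length(missing))
      stop("unknown feature column(s): ", paste(missing, collapse = ", "))
    return(config)
  }
  switch(config,
    dem = DEM_COLUMNS,
    dem_lv = c(DEM_COLUMNS, "lesion_volume"),
    dem_latv = c(DEM_COLUMNS, "lesion_volume", "left_volume", "right_volume"),
    atlas = c(DEM_COLUMNS, "lesion_volume", damage_columns(records)))
}

#' Build the feature matrix for a configuration
#'
#' @inheritParams feature_columns
#' @return Numeric matrix with one row per record.
#' @export
feature_matrix <- function(records, config = "atlas") {
  cols <- feature_columns(records, config)
  X <- as.matrix(as.data.frame(records)[cols])
  storage.mode(X) <- "double"
  X
}

config_label <- function(config) {
  if (length(config) == 1 && config %in% c("dem", "dem_lv", "dem_latv", "atlas"))
    config
  else sprintf("subset_%d", length(config))
}
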