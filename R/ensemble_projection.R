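# Consensus construction: median ensemble across replicate models and
# algorithms, max(se+sp) binarisation, then scenario consensus taken GCM
# first (per-cell median) and SSP second (2-of-3 vote at 0.34).

#' Scenario identifier
#'
#' @param period \code{"present"}, \code{"2030"}, \code{"2050"},
#'   \code{"2070"} or \code{"2090"}.
#' @param gcm Global climate model label (future periods only).
#' @param ssp Emissions pathway label (future periods only).
#' @return A \code{scenario_key}.
#' @export
scenario_key <- function(period, gcm = NA_character_, ssp = NA_character_) {
  period <- as.character(period)
  if (period == "present" && (!is.na(gcm) || !is.na(ssp)))
    stop("the present scenario carries no GCM or SSP")
  if (period != "present" && (is.na(gcm) || is.na(ssp)))
    stop("future scenarios need both a GCM and an SSP")
  structure(list(gcm = gcm, ssp = ssp, period = period),
            class = "scenario_key")
}

scenario_label <- function(key) {
  if (is.null(key)) return("unknown")
  if (key$period == "present") "present"
  else paste(key$gcm, key$ssp, key$period, sep = "_")
}

map_stack_array <- function(maps) {
  spec <- maps[[1]]$spec
  for (m in maps[-1]) stop_unless_coregistered(spec, m$spec)
  array(unlist(lapply(maps, `[[`, "values")),
        dim = c(spec$n_rows, spec$n_cols, length(maps)))
}

cellwise_median <- function(maps) {
  arr <- map_stack_array(maps)
  m <- matrix(arr, nrow = dim(arr)[1] * dim(arr)[2], ncol = dim(arr)[3])
  med <- apply(m, 1, function(r) if (anyNA(r)) NA_real_ else stats::median(r))
  matrix(med, dim(arr)[1], dim(arr)[2])
}

#' Median consensus of suitability maps
#'
#' Per-cell median across all replicate-model maps of all algorithms (the
#' even-count median is the mean of the central pair). A cell is nodata if
#' any input is nodata there.
#'
#' @param maps List of co-registered [suitability_map()]s (>= 1).
#' @return A [suitability_map()].
#' @export
ensemble_median <- function(maps) {
  stopifnot(length(maps) >= 1)
  suitability_map(cellwise_median(maps), maps[[1]]$spec,
                  provenance = list(kind = "ensemble_median",
                                    n_inputs = length(maps)))
}

#' Binarise a suitability map
#'
#' @param map A [suitability_map()].
#' @param threshold Threshold in [0, 1]; a cell is suitable iff its value is
#'   >= threshold. Nodata propagates.
#' @param scenario Optional [scenario_key()] recorded on the result.
#' @return A [binary_map()] recording the threshold used.
#' @export
binarize <- function(map, threshold, scenario = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  binary_map((map$values >= threshold) * 1, map$spec, threshold = threshold,
             scenario = scenario)
}

#' Consensus across global climate models
#'
#' Per-cell median of suitability maps that share the same SSP and period
#' but come from different GCMs.
#'
#' @param per_gcm List of co-registered [suitability_map()]s.
#' @return A [suitability_map()].
#' @export
gcm_consensus <- function(per_gcm) {
  stopifnot(length(per_gcm) >= 1)
  keys <- lapply(per_gcm, function(m) m$provenance$scenario)
  if (all(!vapply(keys, is.null, logical(1)))) {
    ssps <- vapply(keys, `[[`, character(1), "ssp")
    periods <- vapply(keys, `[[`, character(1), "period")
    if (length(unique(ssps)) > 1 || length(unique(periods)) > 1)
      stop("gcm_consensus inputs must share SSP and period")
  }
  suitability_map(cellwise_median(per_gcm), per_gcm[[1]]$spec,
                  provenance = list(kind = "gcm_consensus",
                                    scenario = keys[[1]]))
}

#' 2-of-3 consensus across emissions pathways
#'
#' A cell is deemed potentially occupied only if at least two of the three
#' SSP binary maps mark it suitable: the per-cell vote mean must reach
#' \code{vote_threshold} (0.34, so 1/3 fails and 2/3 passes).
#'
#' @param binary_per_ssp List of exactly 3 co-registered [binary_map()]s.
#' @param vote_threshold Mean-vote cutoff (default 0.34).
#' @param scenario Optional [scenario_key()] for the result.
#' @return A [binary_map()].
#' @export
ssp_consensus <- function(binary_per_ssp, vote_threshold = 0.34,
                          scenario = NULL) {
  if (length(binary_per_ssp) != 3)
    stop("ssp_consensus expects exactly 3 binary maps")
  for (m in binary_per_ssp)
    if (!is_binary_map(m)) stop("ssp_consensus inputs must be binary maps")
  arr <- map_stack_array(binary_per_ssp)
  votes <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  binary_map((votes >= vote_threshold) * 1, binary_per_ssp[[1]]$spec,
             threshold = vote_threshold, scenario = scenario)
}
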