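# Growth-curve and plate phenotyping: trapezoid AUC, replicate means,
# per-gram normalization, RPKM, condition panel comparison.

#' Trapezoid area under a growth curve
#'
#' Trapezoidal integral of optical density over the recorded window (no
#' extrapolation), the standard proxy for cumulative growth or metabolic
#' activity from plate-reader series. Optional blank subtraction removes
#' the first reading from every point before integration, flooring negative
#' values at zero; the default integrates raw OD.
#'
#' @param times acquisition times in hours, strictly increasing, length
#'   >= 2.
#' @param od optical-density readings (>= 0), same length as `times`.
#' @param blank_subtract subtract the first reading before integrating?
#' @return Area in OD x hours.
#' @export
auc_trapezoid <- function(times, od, blank_subtract = FALSE) {
  if (length(times) < 2) stop("AUC needs >= 2 timepoints")
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (blank_subtract) od <- pmax(0, od - od[1])
  pracma::trapz(times, od)
}

#' Mean AUC over replicates
#'
#' One AUC per (sample, condition) group: the arithmetic mean of the
#' per-replicate trapezoid AUCs, with the replicate count reported.
#'
#' @param curves long-format data.frame with columns `sample_id`,
#'   `condition_id`, `replicate_id`, `time`, `od`.
#' @param blank_subtract passed to [auc_trapezoid()].
#' @return data.frame: `sample_id`, `condition_id`, `auc`, `n_replicates`.
#' @export
replicate_mean_auc <- function(curves, blank_subtract = FALSE) {
  grp <- interaction(curves$sample_id, curves$condition_id,
                     curves$replicate_id, drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(curves, grp), function(df) {
    df <- df[order(df$time), ]
    data.frame(sample_id = df$sample_id[1], condition_id = df$condition_id[1],
               auc = auc_trapezoid(df$time, df$od, blank_subtract),
               stringsAsFactors = FALSE)
  }))
  out <- stats::aggregate(auc ~ sample_id + condition_id, data = per_rep,
                          FUN = mean)
  cnt <- stats::aggregate(list(n_replicates = per_rep$auc),
                          by = per_rep[, c("sample_id", "condition_id")],
                          FUN = length)
  merge(out, cnt, by = c("sample_id", "condition_id"))
}

#' Normalize a fecal measurement per gram
#'
#' Used for lipocalin-2 concentrations and CFU counts, which are divided by
#' the wet feces weight of the sample.
#'
#' @param raw_value measured quantity.
#' @param feces_weight sample weight in grams (> 0).
#' @return list: `raw_value`, `feces_weight`, `value_per_gram`.
#' @export
per_gram <- function(raw_value, feces_weight) {
  if (any(feces_weight <= 0)) stop("feces_weight must be > 0")
  list(raw_value = raw_value, feces_weight = feces_weight,
       value_per_gram = raw_value / feces_weight)
}

#' Reads per kilobase per million mapped reads
#'
#' `read_count * 1e9 / (gene_length_bp * total_mapped_reads)`, the length-
#' and depth-normalized expression proxy.
#'
#' @param read_count mapped reads on the gene.
#' @param gene_length_bp gene length in base pairs (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  read_count * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Compare a condition AUC panel between groups
#'
#' Delegates to [feature_scan()]: per-condition two-sample rank test with
#' Benjamini-Hochberg correction across the panel, directions annotated
#' (e.g. `higher-in-WT` on an antibiotic condition flags a KO sensitivity).
#'
#' @param auc_matrix samples x conditions AUC matrix (complete).
#' @param groups two-level factor aligned with rows.
#' @return As [feature_scan()].
#' @export
condition_compare <- function(auc_matrix, groups) {
  if (any(is.na(auc_matrix))) stop("AUC matrix must be complete")
  feature_scan(auc_matrix, groups)
}

#' Read plate-reader OD series
#'
#' Long dialect: columns `sample_id`, `condition_id`, `replicate_id`,
#' `time`, `od`. Wide dialect: a time column followed by one column per
#' well, plus a plate map (`well`, `sample_id`, `condition_id`,
#' `replicate_id`); times may be in hours or minutes.
#'
#' @param path CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param plate_map data.frame mapping wells (wide dialect only).
#' @param time_unit `"hours"` or `"minutes"` (wide dialect only).
#' @return Long-format data.frame as in [replicate_mean_auc()].
#' @export
read_plate_csv <- function(path, dialect = c("long", "wide"),
                           plate_map = NULL,
                           time_unit = c("hours", "minutes")) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "condition_id", "replicate_id", "time", "od")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("missing column(s): ", paste(missing, collapse = ", "))
    return(df[, need])
  }
  if (is.null(plate_map)) stop("wide dialect requires a plate_map")
  tcol <- names(df)[1]
  times <- df[[tcol]]
  if (time_unit == "minutes") times <- times / 60
  wells <- setdiff(names(df), tcol)
  unknown <- setdiff(wells, plate_map$well)
  if (length(unknown))
    stop("wells absent from plate map: ", paste(unknown, collapse = ", "))
  do.call(rbind, lapply(wells, function(w) {
    pm <- plate_map[plate_map$well == w, ]
    data.frame(sample_id = pm$sample_id, condition_id = pm$condition_id,
               replicate_id = pm$replicate_id, time = times, od = df[[w]],
               stringsAsFactors = FALSE)
  }))
}
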