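# Variant-table operations: de-novo filtering, parallelism, persistence.

variant_cols <- c("mouse_id", "week", "locus_id", "position", "ref", "alt",
                  "frequency")

validate_variant_calls <- function(df, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  missing <- setdiff(variant_cols, names(df))
  if (length(missing))
    stop("missing variant columns", where, ": ", paste(missing, collapse = ", "))
  bad <- which(df$frequency < 0 | df$frequency > 1)
  if (length(bad))
    stop("frequency outside [0,1]", where, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$position < 1)
  if (length(bad))
    stop("position must be >= 1", where, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$mouse_id, df$week, df$position, df$alt)
  if (anyDuplicated(key))
    stop("duplicate (mouse, week, position, alt) records", where)
  df
}

#' Read a variant table
#'
#' Two dialects are supported: `tsv` (columns `mouse_id`, `week`,
#' `locus_id`, `position`, `ref`, `alt`, `frequency`, as written by the
#' synthetic-data module) and `genomediff-subset`, a read-only parser for
#' the SNP/INS/DEL records of breseq GenomeDiff (.gd) files that carry a
#' `frequency=` attribute. Parsed calls are validated: frequencies in
#' `[0, 1]`, positions >= 1, unique `(mouse, week, position, alt)` keys.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"genomediff-subset"`.
#' @param mouse_id,week sample identity attached to GenomeDiff records
#'   (which carry none themselves); ignored for `tsv`.
#' @return data.frame of validated variant calls.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "genomediff-subset"),
                               mouse_id = NA_character_, week = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE),
      warning = function(w) stop("malformed variant TSV ", path, ": ",
                                 conditionMessage(w)))
    if (!is.numeric(df$frequency) || !is.numeric(df$position))
      stop("malformed variant TSV ", path,
           ": position and frequency must be numeric")
    return(validate_variant_calls(df, path))
  }
  lines <- readLines(path)
  recs <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    if (!grepl("^(SNP|INS|DEL)\t", ln)) return(NULL)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      stop("malformed GenomeDiff record at line ", i, " of ", path)
    type <- f[1]
    pos <- suppressWarnings(as.numeric(f[5]))
    if (is.na(pos)) stop("non-numeric position at line ", i, " of ", path)
    kv <- f[grepl("=", f, fixed = TRUE)]
    attrs <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    if (!"frequency" %in% names(attrs)) return(NULL)  # consensus record
    freq <- suppressWarnings(as.numeric(attrs[["frequency"]]))
    if (is.na(freq)) stop("non-numeric frequency at line ", i, " of ", path)
    alt <- switch(type, SNP = f[6], INS = f[6], DEL = paste0("del", f[6]))
    locus <- if ("gene_name" %in% names(attrs)) attrs[["gene_name"]] else "."
    data.frame(mouse_id = mouse_id, week = week, locus_id = locus,
               position = pos, ref = ".", alt = alt, frequency = freq,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  if (is.null(df)) df <- data.frame(mouse_id = character(), week = numeric(),
                                    locus_id = character(), position = numeric(),
                                    ref = character(), alt = character(),
                                    frequency = numeric())
  validate_variant_calls(df, path)
}

#' Variant filter configuration
#'
#' The detection floor applied to population-sequencing calls. The default
#' keeps calls at frequency >= 0.05 (inclusive), the operative minimum
#' detection frequency; set `inclusive = FALSE` for a strictly-greater rule.
#'
#' @param min_frequency detection threshold in (0, 1).
#' @param inclusive keep calls equal to the threshold?
#' @export
variant_filter_config <- function(min_frequency = 0.05, inclusive = TRUE) {
  if (min_frequency <= 0 || min_frequency >= 1)
    stop_invalid("min_frequency must lie in (0, 1)")
  structure(list(min_frequency = min_frequency, inclusive = inclusive),
            class = "variant_filter_config")
}

#' Subtract inoculum standing variants
#'
#' Removes calls whose `(position, alt)` key occurs in the inoculum table,
#' leaving de-novo mutations. A different alternate allele at the same
#' position is retained (distinct mutations). Frequencies are untouched.
#' Idempotent; never increases the call count.
#'
#' @param sample_calls variant calls from an evolved population.
#' @param inoculum_calls standing variants of the founding inoculum (same
#'   reference coordinates).
#' @return The de-novo subset of `sample_calls`.
#' @export
subtract_inoculum <- function(sample_calls, inoculum_calls) {
  if (nrow(sample_calls) == 0 || nrow(inoculum_calls) == 0) return(sample_calls)
  key <- paste(sample_calls$position, sample_calls$alt)
  inoc_key <- paste(inoculum_calls$position, inoculum_calls$alt)
  sample_calls[!(key %in% inoc_key), , drop = FALSE]
}

#' Apply the detection-frequency threshold
#'
#' @param calls variant calls.
#' @param cfg a [variant_filter_config()].
#' @return Calls at or above (or strictly above, if `inclusive = FALSE`)
#'   the threshold.
#' @export
apply_frequency_threshold <- function(calls, cfg = variant_filter_config()) {
  keep <- if (cfg$inclusive) calls$frequency >= cfg$min_frequency
          else calls$frequency > cfg$min_frequency
  calls[keep, , drop = FALSE]
}

#' De-novo calls for a whole cohort
#'
#' Convenience wrapper over [subtract_inoculum()] and
#' [apply_frequency_threshold()]: for every mouse, removes the standing
#' variants of its own inoculum, then applies the detection threshold.
#'
#' @param calls variant calls for all mice.
#' @param inoculum_calls per-inoculum standing variants (column
#'   `inoculum_id`).
#' @param cohort cohort design mapping `mouse_id` to `inoculum_id`.
#' @param cfg a [variant_filter_config()].
#' @return Filtered de-novo calls.
#' @export
de_novo_calls <- function(calls, inoculum_calls, cohort,
                          cfg = variant_filter_config()) {
  out <- lapply(split(calls, calls$mouse_id), function(sc) {
    inoc_id <- cohort$inoculum_id[match(sc$mouse_id[1], cohort$mouse_id)]
    if (is.na(inoc_id)) stop("mouse absent from cohort: ", sc$mouse_id[1])
    ic <- inoculum_calls[inoculum_calls$inoculum_id == inoc_id, , drop = FALSE]
    subtract_inoculum(sc, ic)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  apply_frequency_threshold(res, cfg)
}

#' Count de-novo mutations per mouse and week
#'
#' Expects calls already inoculum-subtracted and thresholded. Sampled
#' mouse-weeks with no surviving calls can be reported as zeros by passing
#' the full design grid.
#'
#' @param calls filtered de-novo calls.
#' @param grid optional data.frame of `(mouse_id, week)` combinations that
#'   were sampled; combinations absent from `calls` get count 0.
#' @return data.frame `mouse_id`, `week`, `n_mutations`.
#' @export
count_de_novo <- function(calls, grid = NULL) {
  agg <- stats::aggregate(list(n_mutations = calls$position),
                          by = list(mouse_id = calls$mouse_id,
                                    week = calls$week), FUN = length)
  if (!is.null(grid)) {
    out <- merge(unique(grid[, c("mouse_id", "week")]), agg,
                 all.x = TRUE, sort = TRUE)
    out$n_mutations[is.na(out$n_mutations)] <- 0L
    return(out)
  }
  agg[order(agg$mouse_id, agg$week), ]
}

#' Detect parallel mutated loci
#'
#' A locus is parallel-mutated when it carries a qualifying call in at least
#' two mice that were gavaged with different inocula — the design rule that
#' prevents ancestral standing variants shared through a common inoculum
#' from masquerading as repeated de-novo evolution. Collapsing is at the
#' locus level (gene or named intergenic region), not position level.
#'
#' @param calls filtered de-novo calls.
#' @param cohort cohort design mapping `mouse_id` to `inoculum_id`.
#' @return data.frame with one row per locus: `locus_id`,
#'   `supporting_mice`, `supporting_inocula` (comma-separated), `n_mice`,
#'   `n_inocula`, `is_parallel`.
#' @export
detect_parallel_loci <- function(calls, cohort) {
  unknown <- setdiff(unique(calls$mouse_id), cohort$mouse_id)
  if (length(unknown))
    stop("mice absent from cohort: ", paste(unknown, collapse = ", "))
  inoc <- stats::setNames(cohort$inoculum_id, cohort$mouse_id)
  by_locus <- split(calls$mouse_id, calls$locus_id)
  out <- lapply(names(by_locus), function(l) {
    mice <- sort(unique(by_locus[[l]]))
    inos <- sort(unique(inoc[mice]))
    data.frame(locus_id = l,
               supporting_mice = paste(mice, collapse = ","),
               supporting_inocula = paste(inos, collapse = ","),
               n_mice = length(mice), n_inocula = length(inos),
               is_parallel = length(inos) >= 2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(locus_id = character(), supporting_mice = character(),
                      supporting_inocula = character(), n_mice = integer(),
                      n_inocula = integer(), is_parallel = logical())
  res[order(res$locus_id), ]
}

#' Persistence of final-week mutations at earlier weeks
#'
#' For each mouse and each week before `final_week`, the fraction of the
#' mouse's final-week mutation set already present at that week. Mutation
#' identity defaults to `(position, alt)`; locus-level matching is
#' available. An empty final-week set yields `NA` with `undefined = TRUE`.
#'
#' @param calls filtered de-novo calls for all weeks.
#' @param final_week the reference (last sampled) week.
#' @param identity `"position"` (key `(position, alt)`) or `"locus"`.
#' @return data.frame `mouse_id`, `week`, `n_final`, `n_present`,
#'   `fraction`, `undefined`.
#' @export
persistence_table <- function(calls, final_week, identity = c("position", "locus")) {
  identity <- match.arg(identity)
  weeks <- sort(unique(calls$week))
  if (length(weeks) < 2) stop("persistence needs >= 2 sampled weeks")
  if (!final_week %in% weeks) stop("final week ", final_week, " not sampled")
  keyfun <- function(df) {
    if (identity == "position") paste(df$position, df$alt) else df$locus_id
  }
  earlier <- weeks[weeks < final_week]
  out <- list()
  for (m in sort(unique(calls$mouse_id))) {
    mc <- calls[calls$mouse_id == m, , drop = FALSE]
    final_set <- unique(keyfun(mc[mc$week == final_week, , drop = FALSE]))
    for (w in earlier) {
      wk_set <- unique(keyfun(mc[mc$week == w, , drop = FALSE]))
      n_final <- length(final_set)
      out[[length(out) + 1L]] <- data.frame(
        mouse_id = m, week = w, n_final = n_final,
        n_present = length(intersect(final_set, wk_set)),
        fraction = if (n_final == 0) NA_real_
                   else length(intersect(final_set, wk_set)) / n_final,
        undefined = n_final == 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mouse-by-locus frequency matrix
#'
#' Builds the feature matrix fed to multivariate group discrimination: rows
#' are mice, columns loci, cells the call frequency. A locus absent from a
#' mouse is 0; multiple calls within one locus for one mouse aggregate by
#' maximum frequency.
#'
#' @param calls filtered de-novo calls.
#' @param mice row universe (defaults to mice present in `calls`).
#' @param loci column universe (defaults to loci present in `calls`).
#' @return numeric matrix `mice x loci`.
#' @export
locus_frequency_matrix <- function(calls, mice = NULL, loci = NULL) {
  if (is.null(mice)) mice <- sort(unique(calls$mouse_id))
  if (is.null(loci)) loci <- sort(unique(calls$locus_id))
  m <- matrix(0, length(mice), length(loci), dimnames = list(mice, loci))
  keep <- calls$mouse_id %in% mice & calls$locus_id %in% loci
  cc <- calls[keep, , drop = FALSE]
  if (nrow(cc)) {
    agg <- stats::aggregate(frequency ~ mouse_id + locus_id, data = cc, FUN = max)
    m[cbind(agg$mouse_id, agg$locus_id)] <- agg$frequency
  }
  m
}
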