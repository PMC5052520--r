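# Wild-type-referenced mutant screening on catalytic key distances. A
# candidate complex passes when BOTH of its key-distance means (e.g.
# D_C8-SG and D_N1-HZ) are strictly shorter than the wild-type
# reference's — the in-silico filter for productive enzyme-substrate
# binding conformations. The verdict uses means only, never SDs: a
# documented limitation of the rule.

#' Wild-type screening reference
#'
#' @param label Reference label, e.g. `"WT-1a"`.
#' @param summaries Named list of two [dist_summary()] objects (one per
#'   key distance, typically `D_C8-SG` and `D_N1-HZ`).
#' @return Object of class `screen_reference`.
#' @export
screen_reference <- function(label, summaries) {
  stopifnot(length(summaries) == 2L,
            all(vapply(summaries, inherits, TRUE, "dist_summary")))
  names(summaries) <- vapply(summaries, function(s) s$label, "")
  structure(list(label = label, summaries = summaries),
            class = "screen_reference")
}

#' Screen a mutant candidate against a wild-type reference
#'
#' Pass iff every candidate key-distance mean is strictly shorter than
#' the reference mean for the same label. Optionally a conservative
#' margin of `k` candidate SDs is required
#' (`candidate mean + k * SD < reference mean`); the default `k = 0`
#' reproduces the plain rule on means.
#'
#' @param candidate Named list of two [dist_summary()] objects, or an
#'   `xbond_analysis` whose summaries carry the same labels as the
#'   reference.
#' @param reference A [screen_reference()] (or an `xbond_analysis`).
#' @param candidate_label Label for the candidate.
#' @param k SD margin multiplier (default 0).
#' @return Object of class `screen_result`: `candidate`, `reference`,
#'   `verdict` (`"pass"`/`"fail"`), `criteria` (per-distance logicals),
#'   `candidate_summaries`, `reference_summaries`.
#' @export
#' @examples
#' ref <- screen_reference("WT", list(dist_summary("D_C8-SG", 7.60, 0.58),
#'                                    dist_summary("D_N1-HZ", 9.06, 1.19)))
#' cand <- list(dist_summary("D_C8-SG", 3.79, 0.21),
#'              dist_summary("D_N1-HZ", 3.46, 0.98))
#' screen_mutant(cand, ref, candidate_label = "H141W")
screen_mutant <- function(candidate, reference, candidate_label = "candidate",
                          k = 0) {
  if (inherits(reference, "xbond_analysis"))
    reference <- screen_reference(reference$label, reference$summaries)
  stopifnot(inherits(reference, "screen_reference"))
  if (inherits(candidate, "xbond_analysis")) {
    candidate_label <- candidate$label
    candidate <- candidate$summaries
  }
  stopifnot(all(vapply(candidate, inherits, TRUE, "dist_summary")))
  names(candidate) <- vapply(candidate, function(s) s$label, "")
  ref_labels <- names(reference$summaries)
  if (!setequal(names(candidate), ref_labels))
    stop("specification error: candidate labels (",
         paste(names(candidate), collapse = ", "),
         ") do not match reference labels (",
         paste(ref_labels, collapse = ", "), ")")
  crit <- vapply(ref_labels, function(lb) {
    cs <- candidate[[lb]]
    cs$mean + k * cs$sd < reference$summaries[[lb]]$mean
  }, TRUE)
  structure(list(candidate = candidate_label,
                 reference = reference$label,
                 verdict = if (all(crit)) "pass" else "fail",
                 criteria = crit,
                 candidate_summaries = candidate[ref_labels],
                 reference_summaries = reference$summaries),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen:", x$candidate, "vs reference", x$reference, "->",
      toupper(x$verdict), "\n")
  for (lb in names(x$criteria)) {
    cs <- x$candidate_summaries[[lb]]
    rs <- x$reference_summaries[[lb]]
    cat(sprintf("  %-10s %6.2f %s %6.2f  [%s]\n", lb, cs$mean,
                if (x$criteria[[lb]]) "<" else ">=", rs$mean,
                if (x$criteria[[lb]]) "ok" else "fail"))
  }
  invisible(x)
}

#' Rank screened candidates
#'
#' Passing candidates come first, ordered by ascending sum of their two
#' key-distance means (shorter combined distances first); ties break
#' lexicographically by candidate label.
#'
#' @param results List of `screen_result` objects.
#' @return The same list, reordered.
#' @export
rank_candidates <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "screen_result")))
  sums <- vapply(results, function(r)
    sum(vapply(r$candidate_summaries, function(s) s$mean, 0)), 0)
  labels <- vapply(results, function(r) r$candidate, "")
  passed <- vapply(results, function(r) r$verdict == "pass", TRUE)
  results[order(!passed, sums, labels)]
}

#' Write a screening table and verdict JSON
#'
#' Emits a TSV (candidate, reference, per-distance means, verdict) and a
#' verdict JSON for a set of screen results.
#'
#' @param results List of `screen_result` objects (ranked or not).
#' @param tsv_path,json_path Output paths; `NULL` skips that output.
#' @return Invisibly, the screening table as a `data.frame`.
#' @export
write_screen_table <- function(results, tsv_path = NULL, json_path = NULL) {
  rows <- lapply(results, function(r) {
    means <- vapply(r$candidate_summaries, function(s) s$mean, 0)
    d <- data.frame(candidate = r$candidate, reference = r$reference,
                    verdict = r$verdict, stringsAsFactors = FALSE)
    for (lb in names(means)) d[[lb]] <- means[[lb]]
    d
  })
  tab <- do.call(rbind, rows)
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      lapply(results, function(r)
        list(candidate = r$candidate, reference = r$reference,
             verdict = r$verdict, criteria = as.list(r$criteria))),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
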