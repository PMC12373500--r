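#' Hypergeometric metabolite-set enrichment
#'
#' Over-representation analysis of a query metabolite list against a
#' collection of metabolite sets, using the detected metabolome as the
#' background universe. Each set is first intersected with the background;
#' the P value is the upper tail \eqn{P[X \ge hits]} of a hypergeometric
#' draw of `|query|` metabolites from the background. No multiplicity
#' adjustment is applied by default; `adjust = TRUE` adds BH-adjusted
#' values.
#'
#' @param query Character vector of altered metabolites; must be a subset
#'   of `background`.
#' @param sets A `"metabolite_sets"` collection ([read_metabolite_sets()]).
#' @param background Character vector: all detected metabolites.
#' @param adjust Add a BH-adjusted P column.
#' @return data.frame sorted by P: `set_name`, `set_size` (in background),
#'   `hits`, `expected`, `p_value` (and `adj_p_value` when requested).
#' @export
enrich <- function(query, sets, background, adjust = FALSE) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop("query metabolite(s) not in background: ",
         paste(outside, collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$members, background)
    K <- length(members)
    hits <- length(intersect(query, members))
    p <- stats::phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = K, hits = hits,
               expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
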