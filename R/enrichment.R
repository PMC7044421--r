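# Metabolite-to-signature assignment and metabolite-set over-representation
# analysis: exact hypergeometric upper tail per set, Benjamini-Hochberg
# control across the sets tested for each signature.

#' Assign metabolites to signatures
#'
#' `argmax_above_uniform` (default) assigns metabolite `i` to signature `s`
#' iff `s` is the unique argmax of the metabolite's appearance probabilities
#' and that probability exceeds the uniform baseline `1/M`; argmax ties leave
#' the metabolite unassigned (reported via a message). `top_n` takes the `n`
#' highest-probability metabolites of each signature (a metabolite may then
#' appear in several lists).
#'
#' @param signatures a `SignatureSet` or column-stochastic M x K matrix.
#' @param rule `"argmax_above_uniform"` or `"top_n"`.
#' @param n list size per signature for `top_n`.
#' @return named list (one character vector of metabolite ids per signature).
#' @export
assign_metabolites <- function(signatures, rule = c("argmax_above_uniform", "top_n"),
                               n = 25) {
  rule <- match.arg(rule)
  sig <- if (inherits(signatures, "SignatureSet")) signatures$signatures else as.matrix(signatures)
  m <- nrow(sig); k <- ncol(sig)
  ids <- rownames(sig) %||% sprintf("met%04d", seq_len(m))
  sig_names <- colnames(sig) %||% sprintf("S%d", seq_len(k))
  if (rule == "top_n") {
    n <- check_count(n, "n")
    n <- min(n, m)
    out <- lapply(seq_len(k), function(s) ids[order(sig[, s], decreasing = TRUE)[seq_len(n)]])
    return(stats::setNames(out, sig_names))
  }
  maxp <- apply(sig, 1, max)
  n_argmax <- rowSums(sig == maxp)
  tied <- n_argmax > 1L
  if (any(tied)) {
    message(sum(tied), " metabolite(s) unassigned due to tied argmax")
  }
  assigned <- !tied & maxp > 1 / m
  which_sig <- max.col(sig, ties.method = "first")
  out <- lapply(seq_len(k), function(s) ids[assigned & which_sig == s])
  stats::setNames(out, sig_names)
}

#' Exact hypergeometric over-representation p-value
#'
#' Probability of observing at least the given overlap between a selected
#' metabolite list and a metabolite set when the list is drawn uniformly
#' without replacement from the universe:
#' `p = P[X >= overlap]`, `X ~ Hypergeometric(|universe|, |set|, |selected|)`,
#' computed as an exact tail sum.
#'
#' @param selected character vector of selected metabolite ids.
#' @param set character vector of set member ids.
#' @param universe character vector of all measurable metabolite ids.
#' @return list with `p`, `overlap`, `expected`, `set_size`, `selected_size`,
#'   `universe_size`.
#' @export
hypergeometric_overrep <- function(selected, set, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  set <- unique(as.character(set))
  if (!all(selected %in% universe)) {
    stop("invalid input: selected metabolite(s) outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 3), collapse = ", "),
         call. = FALSE)
  }
  if (!all(set %in% universe)) {
    stop("invalid input: set member(s) outside the universe: ",
         paste(utils::head(setdiff(set, universe), 3), collapse = ", "),
         call. = FALSE)
  }
  nu <- length(universe); ns <- length(set); nl <- length(selected)
  ov <- length(intersect(selected, set))
  # exact upper tail P[X >= ov]
  p <- if (ov == 0L) 1.0 else stats::phyper(ov - 1L, ns, nu - ns, nl, lower.tail = FALSE)
  list(p = min(p, 1.0), overlap = ov, expected = nl * ns / nu,
       set_size = ns, selected_size = nl, universe_size = nu)
}

#' Over-representation analysis of all sets against all signature lists
#'
#' Runs [hypergeometric_overrep()] for every set in the library against each
#' signature's selected metabolite list and appends Benjamini-Hochberg
#' q-values across the sets tested within each signature. An empty selected
#' list yields p = 1 for every set (with a warning).
#'
#' @param lists named list of selected metabolite id vectors (one per
#'   signature), e.g. from [assign_metabolites()].
#' @param library a [pathway_library()]; its universe is the sampling frame.
#' @return object of class `EnrichmentResult`: a data.frame with columns
#'   `signature`, `set`, `set_size`, `selected_size`, `overlap`, `expected`,
#'   `p`, `q`, sorted by signature then p.
#' @export
enrich_all <- function(lists, library) {
  stopifnot(inherits(library, "PathwayLibrary"))
  if (length(library$sets) == 0L) stop("pathway library has no sets", call. = FALSE)
  res <- do.call(rbind, lapply(names(lists), function(sig_name) {
    sel <- intersect(lists[[sig_name]], library$universe)
    if (length(sel) == 0L) {
      warning("empty selected list for ", sig_name, "; all p = 1", call. = FALSE)
    }
    rows <- do.call(rbind, lapply(names(library$sets), function(set_name) {
      h <- hypergeometric_overrep(sel, library$sets[[set_name]], library$universe)
      data.frame(signature = sig_name, set = set_name, set_size = h$set_size,
                 selected_size = h$selected_size, overlap = h$overlap,
                 expected = h$expected, p = h$p, stringsAsFactors = FALSE)
    }))
    rows$q <- stats::p.adjust(rows$p, method = "BH")
    rows[order(rows$p), ]
  }))
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
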