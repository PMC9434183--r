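#' All-pairs Pearson correlation with significance
#'
#' Computes pairwise Pearson correlations over every pair of variables using
#' pairwise-complete observations, together with two-sided p-values from the
#' exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees
#' of freedom, where `n` is the number of complete pairs for that entry.
#'
#' @param data A data frame or matrix with samples in rows and variables in
#'   columns (one column per metabolite/transcript).
#' @param min_pairs Minimum number of complete observation pairs for a
#'   correlation to be reported (at least 3).
#' @return An object of class `correlation_result`: a list with symmetric
#'   matrices `r`, `p`, and `n_used`. Use [tidy()] for a long tibble.
#' @export
#' @examples
#' set.seed(1)
#' x <- tibble::tibble(a = rnorm(10), b = rnorm(10))
#' tidy(pairwise_pearson(x))
pairwise_pearson <- function(data, min_pairs = 3) {
  x <- as.matrix(data)
  if (!is.numeric(x)) abort("All variable columns must be numeric.")
  if (nrow(x) < 3) abort("At least 3 samples are required.")
  if (min_pairs < 3) abort("`min_pairs` must be at least 3.")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  vars <- colnames(x)
  zero_var <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE)) == 0
  zero_var[is.na(zero_var)] <- TRUE
  if (any(zero_var)) {
    warn(sprintf("Zero-variance variable(s): %s; their correlations are NA.",
                 paste(vars[zero_var], collapse = ", ")))
  }
  suppressWarnings(r <- cor(x, use = "pairwise.complete.obs"))
  n_used <- crossprod(!is.na(x))
  r[n_used < min_pairs] <- NA
  r[zero_var, ] <- NA
  r[, zero_var] <- NA
  diag(r) <- ifelse(zero_var, NA, 1)
  tstat <- r * sqrt(pmax(n_used - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = pmax(n_used - 2, 1))
  p[!is.finite(tstat)] <- 0 # |r| = 1 exactly
  p[is.na(r)] <- NA
  diag(p) <- NA
  structure(
    list(variables = vars, r = r, p = p, n_used = n_used,
         min_pairs = min_pairs),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d variables, %d pairs\n",
              length(x$variables), choose(length(x$variables), 2)))
  invisible(x)
}

# upper-triangle long view
cor_pairs <- function(result) {
  vars <- result$variables
  idx <- which(upper.tri(result$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    r = result$r[idx],
    p = result$p[idx],
    n = as.integer(result$n_used[idx])
  )
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) cor_pairs(x)

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  pr <- cor_pairs(x)
  tibble::tibble(
    n_variables = length(x$variables),
    n_pairs = nrow(pr),
    n_reported = sum(!is.na(pr$r))
  )
}

#' Summary counts of a correlation analysis
#'
#' Counts, over all variable pairs: the number of testable ("possible")
#' correlations, how many are significant at `p_max`, and how many of the
#' significant ones are strongly positive (r above `r_hi`) or strongly negative
#' (r below `r_lo`). Threshold comparisons are strict, so pairs sitting exactly at
#' a threshold are excluded.
#'
#' @param result A `correlation_result`.
#' @param p_max Significance level (pairs with `p <= p_max` count).
#' @param r_hi Strong-positive threshold on r.
#' @param r_lo Strong-negative threshold on r (negative number).
#' @return A one-row tibble with `n_possible`, `n_significant`,
#'   `n_strong_pos`, `n_strong_neg`.
#' @export
count_summary <- function(result, p_max = 0.05, r_hi = 0.65, r_lo = -0.65) {
  if (p_max <= 0 || p_max > 1) abort("`p_max` must be in (0, 1].")
  if (r_lo >= r_hi) abort("`r_lo` must be below `r_hi`.")
  pr <- cor_pairs(result)
  ok <- !is.na(pr$r) & pr$n >= result$min_pairs
  sig <- ok & pr$p <= p_max
  tibble::tibble(
    n_possible = sum(ok),
    n_significant = sum(sig),
    n_strong_pos = sum(sig & pr$r > r_hi),
    n_strong_neg = sum(sig & pr$r < r_lo)
  )
}

new_correlation_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build a thresholded correlation network
#'
#' Keeps an edge between two variables iff its correlation is significant
#' (`p <= p_max`) and exceeds the threshold in the requested direction
#' (strictly r above `r_min` for positive edges, below `-r_min` for negative,
#' either for `"both"`). Node degree and betweenness centrality
#' (shortest-path, unweighted, unnormalised) are computed on the resulting
#' graph; nodes with no edges are dropped.
#'
#' @param result A `correlation_result`.
#' @param r_min Correlation magnitude threshold (strict).
#' @param p_max Significance level.
#' @param sign `"positive"`, `"negative"`, or `"both"`.
#' @param classes Optional named character vector mapping variable id to a
#'   class/annotation carried onto the nodes.
#' @return A `correlation_network` with `nodes` (id, class, degree,
#'   betweenness) and `edges` (source, target, r, p, sign) tibbles.
#' @export
build_network <- function(result, r_min, p_max = 0.05,
                          sign = c("positive", "negative", "both"),
                          classes = NULL) {
  sign <- match.arg(sign)
  if (r_min < 0 || r_min > 1) abort("`r_min` must be in [0, 1].")
  pr <- cor_pairs(result)
  pr <- pr[!is.na(pr$r) & !is.na(pr$p) & pr$p <= p_max, ]
  keep <- switch(sign,
    positive = pr$r > r_min,
    negative = pr$r < -r_min,
    both = abs(pr$r) > r_min
  )
  edges <- pr[keep, ]
  edges <- tibble::tibble(
    source = edges$var1, target = edges$var2,
    r = edges$r, p = edges$p,
    sign = ifelse(edges$r > 0, "positive", "negative")
  )
  if (nrow(edges) == 0) {
    nodes <- tibble::tibble(id = character(), class = character(),
                            degree = integer(), betweenness = numeric())
    return(new_correlation_network(nodes, edges))
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ids <- igraph::V(g)$name
  nodes <- tibble::tibble(
    id = ids,
    class = if (is.null(classes)) NA_character_ else unname(classes[ids]),
    degree = as.integer(deg[ids]),
    betweenness = as.numeric(btw[ids])
  )
  new_correlation_network(nodes, edges)
}

#' @method tidy correlation_network
#' @export
tidy.correlation_network <- function(x, ...) x$edges

#' @method glance correlation_network
#' @export
glance.correlation_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    mean_degree = if (nrow(x$nodes)) mean(x$nodes$degree) else NA_real_,
    max_betweenness = if (nrow(x$nodes)) max(x$nodes$betweenness) else NA_real_
  )
}

#' Transcript-metabolite correlation network within a developmental phase
#'
#' Joins transcript and metabolite profiles on shared samples, restricts to a
#' developmental phase (the anthesis stage is shared by both phase windows,
#' mirroring the convention that the preanthesis window runs up to and
#' includes flower opening and the postanthesis window starts there), then
#' computes all pairwise correlations -- gene-gene, gene-metabolite, and
#' metabolite-metabolite -- and keeps positive edges above `r_min`.
#'
#' @param transcripts Data frame/matrix, samples in rows, genes in columns.
#' @param metabolites Data frame/matrix, samples in rows, compounds in columns.
#' @param sample_info Data frame with one row per sample (same order as the
#'   rows of both matrices) carrying a `phase` column.
#' @param phase `"preanthesis"` or `"postanthesis"`.
#' @param include_anthesis Include the anthesis-stage samples in the subset.
#' @param r_min Positive-correlation threshold (strict).
#' @param p_max Significance level.
#' @param classes Optional named class vector for metabolite nodes; gene
#'   nodes are annotated `"gene"`.
#' @return A `correlation_network`; node `class` distinguishes genes from
#'   compound classes.
#' @export
transcript_metabolite_network <- function(transcripts, metabolites, sample_info,
                                          phase = c("preanthesis", "postanthesis"),
                                          include_anthesis = TRUE,
                                          r_min = 0.80, p_max = 0.05,
                                          classes = NULL) {
  phase <- match.arg(phase)
  transcripts <- as.matrix(transcripts)
  metabolites <- as.matrix(metabolites)
  if (nrow(transcripts) != nrow(metabolites) ||
      nrow(transcripts) != nrow(sample_info)) {
    abort("Transcripts, metabolites and `sample_info` must share sample rows.")
  }
  keep_phase <- sample_info$phase == phase
  if (include_anthesis) keep_phase <- keep_phase | sample_info$phase == "anthesis"
  if (sum(keep_phase) < 3) abort("Phase subset has fewer than 3 samples.")
  combined <- cbind(transcripts[keep_phase, , drop = FALSE],
                    metabolites[keep_phase, , drop = FALSE])
  res <- pairwise_pearson(combined)
  node_classes <- c(
    setNames(rep("gene", ncol(transcripts)), colnames(transcripts)),
    if (is.null(classes)) {
      setNames(rep("metabolite", ncol(metabolites)), colnames(metabolites))
    } else {
      classes
    }
  )
  build_network(res, r_min = r_min, p_max = p_max, sign = "positive",
                classes = node_classes)
}
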