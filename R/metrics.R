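# Individualized deviation metrics: outlier maps, total outlier count,
# regional outlier proportions, Hamming-distance dissimilarity.

#' Binarize deviations into atrophy outliers
#'
#' A region is an outlier when its deviation z-score falls strictly below a
#' negative threshold (default -1.96, the lower 2.5% tail of the standard
#' normal; a common liberal alternative is -1.282, the lower 10% tail).
#' Only the lower tail is flagged by default, because the metrics target
#' atrophy; `two_tailed = TRUE` additionally flags `z > |threshold|`.
#'
#' @param dev A `deviation_table` from [predict_zscores()], or a bare
#'   numeric matrix of z-scores (rows = participants).
#' @param threshold Negative z threshold; strict `<` comparison.
#' @param two_tailed Also flag symmetric positive deviations (off by
#'   default).
#' @return An `outlier_table`: list with `ids`, `regions`, binary matrix
#'   `o` (0/1 integers) and `threshold`.
#' @export
binarize_outliers <- function(dev, threshold = -1.96, two_tailed = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold >= 0)
    stop("parameter error: `threshold` must be a negative z-value", call. = FALSE)
  z <- if (inherits(dev, "deviation_table")) dev$z else as.matrix(dev)
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  o <- (z < threshold)
  if (two_tailed) o <- o | (z > -threshold)
  mode(o) <- "integer"
  structure(list(ids = rownames(z) %||% as.character(seq_len(nrow(z))),
                 regions = colnames(z) %||% as.character(seq_len(ncol(z))),
                 o = o, threshold = threshold),
            class = "outlier_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-participant deviation summaries
#'
#' Total outlier count (number of outlier regions across the full index;
#' the individualized neurodegeneration summary) and the mean regional
#' z-score.
#'
#' @param dev A `deviation_table` (or z matrix).
#' @param out An `outlier_table` from [binarize_outliers()]; computed at the
#'   default threshold if omitted.
#' @return Data frame: `participant_id`, `total_outlier_count`,
#'   `mean_regional_z`.
#' @export
summarize_participants <- function(dev, out = binarize_outliers(dev)) {
  z <- if (inherits(dev, "deviation_table")) dev$z else as.matrix(dev)
  if (!identical(dim(z), dim(out$o)))
    stop("shape error: z matrix is ", paste(dim(z), collapse = "x"),
         " but outlier matrix is ", paste(dim(out$o), collapse = "x"),
         call. = FALSE)
  data.frame(participant_id = out$ids,
             total_outlier_count = as.integer(rowSums(out$o)),
             mean_regional_z = rowMeans(z),
             stringsAsFactors = FALSE)
}

#' Regional outlier proportions by group
#'
#' For each region, the proportion of participants within each group whose
#' deviation is an outlier — the tabular form of a regional outlier map.
#'
#' @param out An `outlier_table`.
#' @param group Group label per participant (recycled against rows of `o`).
#' @return List with `proportions` (data frame, region rows in canonical
#'   order, one column per group) and `peaks` (per group: the region with
#'   the highest outlier count, that count, and the proportion).
#' @export
regional_outlier_proportion <- function(out, group) {
  stopifnot(inherits(out, "outlier_table"))
  group <- as.character(group)
  if (length(group) != nrow(out$o))
    stop("`group` must have one label per participant", call. = FALSE)
  groups <- unique(group)
  prop <- vapply(groups, function(g)
    colMeans(out$o[group == g, , drop = FALSE]), numeric(ncol(out$o)))
  prop <- as.data.frame(matrix(prop, ncol = length(groups),
                               dimnames = list(NULL, groups)))
  peaks <- do.call(rbind, lapply(groups, function(g) {
    counts <- colSums(out$o[group == g, , drop = FALSE])
    j <- which.max(counts)
    data.frame(group = g, region = out$regions[j],
               n_outliers = as.integer(counts[j]),
               proportion = counts[j] / sum(group == g),
               stringsAsFactors = FALSE)
  }))
  list(proportions = cbind(data.frame(region = out$regions,
                                      stringsAsFactors = FALSE), prop),
       peaks = peaks)
}

#' Within-group Hamming-distance dissimilarity
#'
#' Pairwise Hamming distances between participants' binary outlier vectors
#' (number of regions where the two vectors differ; 0 to the number of
#' regions), computed within each group, plus each participant's median
#' distance to the other group members (median rather than mean, as the
#' distance distributions are right-skewed; the median over an even count
#' is the mean of the two middle values).
#'
#' @param out An `outlier_table`.
#' @param group Group label per participant.
#' @return Named list (one element per group) of `hamming_result`s: integer
#'   `distances` matrix with participant ids as dimnames, and `medians`
#'   data frame (`participant_id`, `median_distance`).
#' @export
hamming_matrix <- function(out, group = rep("all", nrow(out$o))) {
  stopifnot(inherits(out, "outlier_table"))
  group <- as.character(group)
  res <- list()
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) < 2L)
      stop("group '", g, "' has a single participant; ",
           "pairwise dissimilarity needs >= 2", call. = FALSE)
    M <- out$o[i, , drop = FALSE]
    # d(i,j) = sum o_i + sum o_j - 2 o_i.o_j for binary vectors
    G <- tcrossprod(M)
    rs <- rowSums(M)
    D <- outer(rs, rs, `+`) - 2 * G
    storage.mode(D) <- "integer"
    dimnames(D) <- list(out$ids[i], out$ids[i])
    med <- vapply(seq_along(i), function(k) stats::median(D[k, -k]), numeric(1))
    res[[g]] <- structure(
      list(distances = D,
           medians = data.frame(participant_id = out$ids[i],
                                median_distance = med,
                                stringsAsFactors = FALSE)),
      class = "hamming_result")
  }
  res
}
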