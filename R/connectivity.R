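#' Pearson correlation matrix of a beta series
#'
#' Pairwise correlation of per-trial amplitude estimates across ROIs; the
#' connectivity matrix of one condition.
#'
#' @param beta `trials x ROI` matrix (one element of a `beta_series`).
#' @param fisher_z If `TRUE`, return Fisher z-transformed values
#'   (off-diagonal); default raw r.
#' @return Symmetric `ROI x ROI` matrix with unit diagonal.
#' @export
beta_corr_matrix <- function(beta, fisher_z = FALSE) {
  beta <- as.matrix(beta)
  beta <- beta[complete.cases(beta), , drop = FALSE]
  if (nrow(beta) < 3)
    stop("at least 3 trials are required for a correlation matrix")
  sds <- apply(beta, 2, sd)
  if (any(sds == 0))
    stop("constant beta series for ROI: ",
         paste(colnames(beta)[sds == 0], collapse = ", "))
  C <- cor(beta)
  if (fisher_z) {
    Z <- atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12))
    diag(Z) <- 1
    C <- Z
  } else diag(C) <- 1
  C
}

roi_networks <- function(C, rois) {
  nets <- rois$network[match(rownames(C), rois$name)]
  if (any(is.na(nets)))
    stop("connectivity matrix rows do not match the ROI table")
  nets
}

#' Mean within-network connectivity
#'
#' Mean of the C(n, 2) unordered off-diagonal pairs among the nodes of one
#' network (21 pairs for a 7-node network).
#'
#' @param C Connectivity matrix with ROI names.
#' @param rois ROI table mapping names to networks.
#' @param network Network label.
#' @return Scalar mean; attribute `n_pairs` carries the pair count.
#' @export
within_network_mean <- function(C, rois, network) {
  nets <- roi_networks(C, rois)
  idx <- which(nets == network)
  if (!length(idx)) stop("unknown network label: ", network)
  if (length(idx) < 2) stop("network '", network, "' has fewer than 2 nodes")
  sub <- C[idx, idx, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  structure(mean(vals), n_pairs = length(vals))
}

#' Mean between-network connectivity
#'
#' Mean over all n_A x n_B cross-network node pairs (49 pairs for two
#' 7-node networks).
#'
#' @inheritParams within_network_mean
#' @param network_a,network_b Distinct network labels.
#' @return Scalar mean with attribute `n_pairs`.
#' @export
between_network_mean <- function(C, rois, network_a, network_b) {
  if (identical(network_a, network_b))
    stop("between-network mean requires two distinct networks")
  nets <- roi_networks(C, rois)
  ia <- which(nets == network_a); ib <- which(nets == network_b)
  if (!length(ia)) stop("unknown network label: ", network_a)
  if (!length(ib)) stop("unknown network label: ", network_b)
  vals <- C[ia, ib, drop = FALSE]
  structure(mean(vals), n_pairs = length(vals))
}

#' Node-level within- and between-network strength
#'
#' For each ROI: mean connectivity to the other nodes of its own network,
#' and mean connectivity to the nodes of the other network(s).
#'
#' @inheritParams within_network_mean
#' @return Data frame: name, network, within_strength, between_strength.
#' @export
node_strengths <- function(C, rois) {
  nets <- roi_networks(C, rois)
  counts <- table(nets)
  if (any(counts < 2))
    stop("singleton network: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  out <- data.frame(name = rownames(C), network = nets,
                    within_strength = NA_real_, between_strength = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(C))) {
    same <- nets == nets[i]
    out$within_strength[i] <- mean(C[i, same & seq_len(ncol(C)) != i])
    out$between_strength[i] <- if (any(!same)) mean(C[i, !same]) else NA_real_
  }
  out
}

#' Average connectivity matrices across conditions
#'
#' Element-wise arithmetic mean of the selected condition matrices (the
#' "collapsed" Peer or Character matrix, or the all-condition average).
#'
#' @param matrices Named list of connectivity matrices.
#' @param which Names to average (default all).
#' @return One matrix.
#' @export
collapse_conditions <- function(matrices, which = names(matrices)) {
  sel <- matrices[which]
  if (any(vapply(sel, is.null, logical(1))))
    stop("unknown condition in 'which'")
  ref <- rownames(sel[[1]])
  for (m in sel)
    if (!identical(rownames(m), ref)) stop("mismatched node sets")
  Reduce(`+`, sel) / length(sel)
}

#' Network summary of one condition's connectivity matrix
#'
#' @inheritParams within_network_mean
#' @return List: `within` (named per network), `between` (named
#'   "A|B" per network pair), `nodes` (from [node_strengths()]).
#' @export
network_summary <- function(C, rois) {
  nets <- unique(rois$network[match(rownames(C), rois$name)])
  within <- vapply(nets, function(nw) within_network_mean(C, rois, nw),
                   numeric(1))
  pairs <- if (length(nets) > 1) utils::combn(nets, 2, simplify = FALSE)
    else list()
  between <- vapply(pairs, function(p)
    between_network_mean(C, rois, p[1], p[2]), numeric(1))
  names(between) <- vapply(pairs, paste, character(1), collapse = "|")
  list(within = within, between = between, nodes = node_strengths(C, rois))
}
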