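#' Direction coherence between two datasets
#'
#' Two measurements of the same event's inclusion change are coherent when
#' they agree in sign. Compared over the intersection of event ids; events
#' with a zero change in either dataset are excluded.
#'
#' @param delta_a,delta_b Named numeric vectors of inclusion changes keyed by
#'   event id.
#' @return List with `n_compared`, `n_coherent`, `fraction`.
#' @export
coherence <- function(delta_a, delta_b) {
  ids <- intersect(names(delta_a), names(delta_b))
  if (length(ids) == 0) stop_arg("no shared event ids")
  a <- delta_a[ids]; b <- delta_b[ids]
  keep <- !is.na(a) & !is.na(b) & a != 0 & b != 0
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop_arg("no shared events with nonzero changes")
  n_coh <- sum(sign(a) == sign(b))
  list(n_compared = length(a), n_coherent = n_coh,
       fraction = n_coh / length(a))
}

misclassification_count <- function(assignment, labels) {
  labs <- unique(labels)
  if (length(labs) != 2) stop_arg("labels must have exactly two classes")
  m1 <- sum((assignment == 1) != (labels == labs[1]))
  min(m1, length(labels) - m1)
}

#' Cluster samples by their inclusion profiles
#'
#' Agglomerative hierarchical clustering of samples on the correlation
#' distance `1 - Pearson(sample_i, sample_j)` with average (UPGMA) linkage,
#' cut into two groups at the top split. When two-class sample labels are
#' supplied, the misclassification count is minimized over the two possible
#' label-to-cluster mappings, so it is invariant to swapping label names.
#'
#' @param panel Numeric matrix, events in rows, samples in columns (`NA` for
#'   missing values).
#' @param labels Optional two-class character/factor vector, one per sample.
#' @param na_action `"complete"` drops events with any missing value before
#'   correlating; `"pairwise"` uses pairwise-complete correlations.
#' @return List with `hclust` (the merge tree), `assignment` (two-group cut,
#'   values 1/2), `misclassifications` (or `NA` without labels) and the
#'   distance matrix `dist`.
#' @export
cluster_samples <- function(panel, labels = NULL,
                            na_action = c("complete", "pairwise")) {
  na_action <- match.arg(na_action)
  if (ncol(panel) < 3) stop_arg("need at least 3 samples")
  if (na_action == "complete") {
    panel <- panel[stats::complete.cases(panel), , drop = FALSE]
    if (nrow(panel) == 0) stop_arg("no events without missing values")
  }
  sds <- apply(panel, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- colnames(panel)[!is.finite(sds) | sds == 0] %||% which(sds == 0)
    stop_arg("constant sample profile, correlation undefined: ",
             paste(bad, collapse = ", "))
  }
  use <- if (na_action == "complete") "everything" else "pairwise.complete.obs"
  d <- stats::as.dist(1 - stats::cor(panel, use = use))
  hc <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(hc, k = 2)
  mis <- if (is.null(labels)) NA_integer_ else {
    misclassification_count(assignment, labels)
  }
  list(hclust = hc, assignment = assignment, misclassifications = mis,
       dist = d)
}

#' Permutation significance of signature-based clustering
#'
#' Compares the misclassification count obtained when clustering samples on a
#' chosen foreground event set against the counts obtained on random event
#' sets of the same size drawn (without replacement) from the full panel. The
#' p-value uses the add-one permutation estimator
#' `p = (1 + #(perm <= observed)) / (n_perm + 1)`, which never returns 0.
#'
#' @param full_panel Events x samples matrix, the randomization universe.
#' @param fg_event_ids Row names of the foreground signature.
#' @param labels Two-class sample labels.
#' @param n_perm Number of random draws (>= 100).
#' @param seed Integer seed; the procedure is reproducible bit for bit.
#' @return List with `observed` misclassifications, `perm` (vector of
#'   permutation counts) and `p`.
#' @export
randomized_cluster_pvalue <- function(full_panel, fg_event_ids, labels,
                                      n_perm = 999, seed = 1) {
  if (n_perm < 100) stop_arg("n_perm must be >= 100")
  if (!all(fg_event_ids %in% rownames(full_panel))) {
    stop_arg("fg_event_ids must be rows of full_panel")
  }
  k <- length(fg_event_ids)
  if (k > nrow(full_panel)) stop_arg("foreground larger than the panel")
  obs <- cluster_samples(full_panel[fg_event_ids, , drop = FALSE],
                         labels)$misclassifications
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rows <- sample(nrow(full_panel), k)
      cluster_samples(full_panel[rows, , drop = FALSE],
                      labels)$misclassifications
    }, numeric(1))
  })
  list(observed = obs, perm = perm,
       p = (1 + sum(perm <= obs)) / (n_perm + 1))
}

#' Normalize a panel to reference samples
#'
#' Divides each event row by the mean of its values over the reference
#' samples (e.g. fibroadenoma controls for a tumor inclusion-ratio panel).
#'
#' @param panel Events x samples matrix.
#' @param ref_samples Column names (or indices) of the reference samples.
#' @return Matrix of the non-reference columns, normalized.
#' @export
normalize_to_reference <- function(panel, ref_samples) {
  ref_mean <- rowMeans(panel[, ref_samples, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(ref_mean) | ref_mean == 0)) {
    stop_arg("reference mean is zero or undefined for some events")
  }
  keep <- if (is.character(ref_samples)) {
    setdiff(colnames(panel), ref_samples)
  } else {
    setdiff(seq_len(ncol(panel)), ref_samples)
  }
  sweep(panel[, keep, drop = FALSE], 1, ref_mean, "/")
}

#' Pairwise event correlation with bootstrap cluster support
#'
#' Computes the event-by-event Pearson correlation matrix across samples
#' (pairwise-complete; pairs with fewer than 3 complete observations are
#' `NA`), clusters the events on `1 - r` with average linkage, and attaches
#' per-branch support as the fraction of ordinary bootstrap resamples
#' (samples drawn with replacement) whose tree contains the same branch.
#' Events that are constant or have no valid correlation are excluded with a
#' notice.
#'
#' @param panel Events x samples matrix (already normalized upstream if a
#'   reference normalization is wanted).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `cor` (full correlation matrix), `hclust`, `phylo`
#'   (ape tree of the clustered events), `support` (per-internal-branch
#'   bootstrap proportions in `hclust` merge order), `excluded` (event ids
#'   dropped).
#' @export
event_correlation_cluster <- function(panel, n_boot = 1000, seed = 1) {
  r <- suppressWarnings(stats::cor(t(panel), use = "pairwise.complete.obs"))
  nobs <- tcrossprod(!is.na(panel))
  r[nobs < 3] <- NA
  usable <- rowSums(!is.na(r)) > 1 & !is.na(diag(r))
  excluded <- rownames(panel)[!usable]
  if (length(excluded) > 0) {
    message("excluding event(s) with undefined correlations: ",
            paste(excluded, collapse = ", "))
  }
  ru <- r[usable, usable, drop = FALSE]
  if (nrow(ru) < 3) stop_arg("need at least 3 events with valid correlations")
  hc <- stats::hclust(stats::as.dist(1 - ru), method = "average")
  tree <- ape::as.phylo(hc)
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      cols <- sample(ncol(panel), replace = TRUE)
      sub <- panel[usable, cols, drop = FALSE]
      rb <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
      rb[!is.finite(rb)] <- 0
      ape::as.phylo(stats::hclust(stats::as.dist(1 - rb), method = "average"))
    })
  })
  support <- if (n_boot > 0) {
    ape::prop.clades(tree, boots, rooted = TRUE) / n_boot
  } else {
    rep(NA_real_, nrow(ru) - 1)
  }
  list(cor = r, hclust = hc, phylo = tree, support = support,
       excluded = excluded)
}

#' Write a dendrogram in newick format
#'
#' @param hc An `hclust` object (or `ape` phylo).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  tree <- if (inherits(hc, "phylo")) hc else ape::as.phylo(hc)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a sample panel from TSV
#'
#' Rows are events, columns are samples, with a header of sample ids and `NA`
#' for missing entries.
#'
#' @param path TSV path.
#' @return Numeric matrix with event row names.
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a sample panel as TSV
#'
#' @param panel Events x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(cbind(event_id = rownames(panel), as.data.frame(panel)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
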