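# ---------------------------------------------------------------------------
# End-to-end experiment orchestration: simulate datasets, derive per-gene
# trees per method, estimate the species tree, score against the truth, and
# compare methods with paired Wilcoxon signed-rank tests under Bonferroni
# correction.
# ---------------------------------------------------------------------------

#' Specify one species-tree estimation method for [run_experiment()]
#'
#' A method is a gene-tree source (the simulated true gene trees, or trees
#' re-estimated from the simulated sequences with logdet + neighbor joining),
#' a point-estimate rule (the full tree; the tree with low-support edges
#' contracted; or the majority/most-frequent-topology summary of the
#' bootstrap sample), and a species-tree method.
#'
#' @param species_method One of `"greedy"`, `"majority"`, `"glass"`, `"mdc"`,
#'   `"dup"`, `"duploss"`.
#' @param gene_tree_source `"true"` (simulated gene trees) or `"internal_nj"`
#'   (logdet + NJ on the simulated alignments).
#' @param point_estimate `"full"`, `"contracted"`, `"majority"`, or `"map"`;
#'   the last three require `gene_tree_source = "internal_nj"`.
#' @param threshold Support threshold for `"contracted"` (default 0.75).
#' @param distance_source For `"glass"`: `"path"` (path distances on the
#'   per-gene trees) or `"logdet"` (logdet matrices from the alignments).
#' @param bootstrap_replicates Bootstrap replicates backing `"contracted"`,
#'   `"majority"` and `"map"`.
#' @param label Display label; a default like `"greedy(NJ-75%)"` is built
#'   when omitted.
#' @return List of class `method_spec`.
#' @export
method_spec <- function(species_method = c("greedy", "majority", "glass",
                                           "mdc", "dup", "duploss"),
                        gene_tree_source = c("true", "internal_nj"),
                        point_estimate = c("full", "contracted", "majority", "map"),
                        threshold = 0.75,
                        distance_source = c("path", "logdet"),
                        bootstrap_replicates = 100,
                        label = NULL) {
  species_method <- match.arg(species_method)
  gene_tree_source <- match.arg(gene_tree_source)
  point_estimate <- match.arg(point_estimate)
  distance_source <- match.arg(distance_source)
  if (gene_tree_source == "true" && point_estimate != "full") {
    abort("point-estimate rules other than 'full' require gene_tree_source = 'internal_nj'")
  }
  if (is.null(label)) {
    src <- if (gene_tree_source == "true") "true" else "NJ"
    pe <- switch(point_estimate,
      full = "", contracted = sprintf("-%d%%", round(threshold * 100)),
      majority = "-maj", map = "-map"
    )
    label <- sprintf("%s(%s%s)", species_method, src, pe)
  }
  structure(
    list(
      species_method = species_method, gene_tree_source = gene_tree_source,
      point_estimate = point_estimate, threshold = threshold,
      distance_source = distance_source,
      bootstrap_replicates = as.integer(bootstrap_replicates), label = label
    ),
    class = "method_spec"
  )
}

# derive the per-gene estimated trees (and matrices, for glass) for a method
derive_gene_inputs <- function(dataset, method, seed) {
  if (method$gene_tree_source == "true") {
    trees <- dataset$gene_trees
  } else {
    if (is.null(dataset$alignments)) abort("dataset has no simulated sequences")
    trees <- lapply(seq_along(dataset$alignments), function(i) {
      aln <- dataset$alignments[[i]]
      switch(method$point_estimate,
        full = nj_tree(suppressWarnings(logdet_distance(aln))),
        contracted = contract_low_support(
          bootstrap_support(aln, method$bootstrap_replicates, seed = seed + i),
          method$threshold
        ),
        majority = ,
        map = point_estimates(
          bootstrap_sample(aln, method$bootstrap_replicates, seed = seed + i),
          kind = method$point_estimate
        )
      )
    })
  }
  out <- list(trees = trees)
  if (method$species_method == "glass") {
    out$matrices <- if (method$distance_source == "path") {
      lapply(trees, tree_path_distances)
    } else {
      if (is.null(dataset$alignments)) abort("logdet distances need simulated sequences")
      lapply(dataset$alignments, function(a) suppressWarnings(logdet_distance(a)))
    }
  }
  out
}

# bootstrap replicate tree sample (logdet + NJ per resampled alignment)
bootstrap_sample <- function(aln, replicates, seed = NULL) {
  m <- check_alignment(as_alignment(aln))
  if (!is.null(seed)) withr::local_seed(seed)
  lapply(seq_len(replicates), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    nj_tree(suppressWarnings(logdet_distance(m[, cols, drop = FALSE])))
  })
}

estimate_species_tree <- function(inputs, method, seed) {
  switch(method$species_method,
    greedy = greedy_consensus(inputs$trees),
    majority = majority_consensus(inputs$trees),
    glass = glass_tree(inputs$matrices),
    mdc = ,
    dup = ,
    duploss = search_species_tree(
      inputs$trees,
      search_config(criterion = method$species_method, seed = seed)
    )$tree
  )
}

#' Run a simulation experiment over datasets and methods
#'
#' For each simulated dataset, derives per-gene trees for every method,
#' estimates the species tree, and scores it against the true species tree
#' with the missing-branch rate. Failures of individual (dataset, method)
#' combinations are recorded as rows with `NA` rate and a note; the sweep
#' continues.
#'
#' @param config An [experiment_config()]; dataset `i` uses seed
#'   `config$seed + i - 1`.
#' @param methods List of [method_spec()] objects (possibly empty).
#' @param n_datasets Number of replicate datasets.
#' @return Tibble with columns `dataset_id`, `n_taxa`, `n_genes`,
#'   `alignment_kind`, `method_label`, `fn_rate`, `note`.
#' @export
run_experiment <- function(config, methods, n_datasets = 1) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(methods) == 0) {
    return(tibble::tibble(
      dataset_id = integer(0), n_taxa = integer(0), n_genes = integer(0),
      alignment_kind = character(0), method_label = character(0),
      fn_rate = numeric(0), note = character(0)
    ))
  }
  needs_seq <- any(vapply(methods, function(m) {
    m$gene_tree_source == "internal_nj" ||
      (m$species_method == "glass" && m$distance_source == "logdet")
  }, logical(1)))
  rows <- list()
  for (i in seq_len(n_datasets)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    dataset <- generate_dataset(cfg_i, with_sequences = needs_seq)
    for (k in seq_along(methods)) {
      method <- methods[[k]]
      seed_ik <- cfg_i$seed * 131L + k
      row <- tryCatch({
        inputs <- derive_gene_inputs(dataset, method, seed_ik)
        est <- estimate_species_tree(inputs, method, seed_ik)
        sc <- missing_branch_rate(dataset$species_tree, est)
        tibble::tibble(fn_rate = sc$fn_rate, note = NA_character_)
      }, error = function(e) {
        tibble::tibble(fn_rate = NA_real_, note = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        dataset_id = i, n_taxa = config$n_taxa, n_genes = config$n_genes,
        alignment_kind = "true", method_label = method$label,
        fn_rate = row$fn_rate, note = row$note
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of the paired differences `a - b`. Zero differences are
#' dropped before ranking. For 12 or fewer non-zero differences the exact
#' null distribution is enumerated over all sign patterns (ties handled via
#' midranks); otherwise the normal approximation with tie correction is used.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) abort("paired vectors differ in length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(1)
  }
  if (n < 5) abort("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(W_all <= W), mean(W_all >= W))
    return(min(1, p))
  }
  wilcoxon_normal_approx(paired_a, paired_b)
}

# normal approximation with tie and continuity corrections
wilcoxon_normal_approx <- function(paired_a, paired_b) {
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; must be at least `length(p_values)`.
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (isTRUE(any(p_values < 0 | p_values > 1, na.rm = TRUE))) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) abort("m must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Pairwise method comparison on a results table
#'
#' For each requested pair of method labels, pairs the FN rates by dataset,
#' runs the two-sided Wilcoxon signed-rank test, and Bonferroni-adjusts over
#' the number of pairs compared.
#'
#' @param table Results tibble from [run_experiment()].
#' @param pairs List of length-2 character vectors of method labels.
#' @return Tibble with one row per pair: labels, number of shared datasets
#'   and of non-zero paired differences, per-method mean FN rates, raw and
#'   Bonferroni-adjusted p-values. Pairs with fewer than 5 non-zero
#'   differences cannot be tested and get `NA` p-values.
#' @export
compare_methods <- function(table, pairs) {
  labs <- unique(table$method_label)
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% labs)) {
      abort(sprintf("unknown method label(s): %s", paste(setdiff(pr, labs), collapse = ", ")))
    }
    a <- table[table$method_label == pr[1] & !is.na(table$fn_rate), c("dataset_id", "fn_rate")]
    b <- table[table$method_label == pr[2] & !is.na(table$fn_rate), c("dataset_id", "fn_rate")]
    shared <- intersect(a$dataset_id, b$dataset_id)
    va <- a$fn_rate[match(shared, a$dataset_id)]
    vb <- b$fn_rate[match(shared, b$dataset_id)]
    p <- tryCatch(
      withCallingHandlers(
        wilcoxon_signed_rank(va, vb),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) NA_real_  # too few non-zero differences to test
    )
    tibble::tibble(
      method_a = pr[1], method_b = pr[2], n_datasets = length(shared),
      n_nonzero = sum(va != vb),
      mean_fn_a = mean(va), mean_fn_b = mean(vb), p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_value, m = length(pairs))
  out
}
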