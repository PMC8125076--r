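# Incompleteness-aware core/accessory partitioning of an mOTU's gene
# clusters. A gene is core when its presence/absence profile is more
# probable under "present in every genome, absences caused by genome
# incompleteness" than under an accessory-pool carriage model.

#' Core-model log-likelihood of a presence/absence profile
#'
#' Probability of observing the profile if the gene is truly in every
#' genome: genome *i* detects it with probability equal to its completeness
#' `c_i`, so `LL = sum_present log(c_i) + sum_absent log(1 - c_i)`.
#' Completeness is clamped to `[eps, 1 - eps]` to keep the result finite.
#'
#' @param presence 0/1 vector (1 = gene observed in the genome).
#' @param completeness completeness fractions, same length as `presence`.
#' @param eps clamping constant (default 1e-3).
#' @return a finite log-probability (<= 0).
#' @examples
#' loglik_core(c(rep(1, 9), 0), rep(0.9, 10))
#' @export
loglik_core <- function(presence, completeness, eps = 1e-3) {
  if (length(presence) != length(completeness)) {
    abort("`presence` and `completeness` must have the same length.")
  }
  c_i <- clamp_prob(completeness, eps)
  sum(ifelse(presence > 0, log(c_i), log(1 - c_i)))
}

#' Accessory-model log-likelihood of a presence/absence profile
#'
#' Probability of the profile if the gene segregates in the accessory pool:
#' genome *i* carries any given accessory gene with probability `p_i` (its
#' observed accessory-gene count over the mOTU's distinct accessory-gene
#' pool size), so `LL = sum_present log(p_i) + sum_absent log(1 - p_i)`.
#'
#' @param presence 0/1 vector.
#' @param carriage per-genome accessory carriage probabilities.
#' @param eps clamping constant.
#' @return a finite log-probability (<= 0).
#' @examples
#' loglik_accessory(c(1, rep(0, 9)), rep(0.3, 10))
#' @export
loglik_accessory <- function(presence, carriage, eps = 1e-3) {
  if (length(presence) != length(carriage)) {
    abort("`presence` and `carriage` must have the same length.")
  }
  p_i <- clamp_prob(carriage, eps)
  sum(ifelse(presence > 0, log(p_i), log(1 - p_i)))
}

# matrix forms used by the iteration (genes x genomes)
ll_core_matrix <- function(M, c_i, eps = 1e-3) {
  c_i <- clamp_prob(c_i, eps)
  drop(M %*% log(c_i) + (1 - M) %*% log(1 - c_i))
}
ll_acc_matrix <- function(M, p_i, eps = 1e-3) {
  p_i <- clamp_prob(p_i, eps)
  drop(M %*% log(p_i) + (1 - M) %*% log(1 - p_i))
}

as_presence_matrix <- function(presence) {
  stopifnot(is.data.frame(presence), "gene" %in% names(presence))
  genomes <- setdiff(names(presence), "gene")
  if (length(genomes) == 0) abort("presence table has no genome columns.")
  M <- as.matrix(presence[, genomes, drop = FALSE])
  if (!all(M %in% c(0, 1))) abort("presence cells must be 0/1.")
  storage.mode(M) <- "double"
  rownames(M) <- presence$gene
  if (anyDuplicated(presence$gene)) abort("duplicate gene labels.")
  M
}

#' Partition an mOTU's genes into core and accessory
#'
#' Iterative likelihood classification. Starting from an initial split
#' (genes observed at frequency at or above the mean completeness are
#' provisional core), the per-genome accessory carriage probabilities `p_i`
#' are computed from the current accessory set, every gene is reassigned by
#' comparing [loglik_core()] against [loglik_accessory()], and the loop
#' repeats to a fixed point (or `max_iter`). If the assignment cycles, the
#' lexicographically smallest assignment in the cycle is returned with
#' `converged = FALSE`. The procedure is deterministic and invariant to
#' gene/genome input order.
#'
#' Genes observed in zero genomes are undefined under this model (the
#' absence evidence standard is "never seen in any member") and are
#' rejected; strip them before calling, or use [motu_traits()] which
#' reports them as `absent`.
#'
#' @param presence wide presence table: a `gene` column plus one 0/1 column
#'   per genome (see [presence_matrix()]).
#' @param completeness per-genome completeness: named vector, single value,
#'   or data frame (genome_id, completeness); fractions or percent.
#' @param max_iter maximum number of reassignment sweeps.
#' @param reestimate_completeness when `TRUE`, completeness is re-estimated
#'   after each sweep as (core genes observed in genome i) / (core genes);
#'   off by default, treating the input (e.g. single-copy-marker estimates)
#'   as authoritative.
#' @param eps clamping constant for probabilities.
#' @return a `gene_partition` object; see [tidy.gene_partition()],
#'   [glance.gene_partition()], [summarize_partition()].
#' @examples
#' pres <- tibble::tibble(gene = c("g1", "g2"), A = c(1L, 1L), B = c(1L, 0L))
#' fit <- classify_genes(pres, completeness = c(A = 0.9, B = 0.9))
#' tidy(fit)
#' @export
classify_genes <- function(presence, completeness, max_iter = 100,
                           reestimate_completeness = FALSE, eps = 1e-3) {
  assert_count(max_iter, "max_iter", min = 1)
  M <- as_presence_matrix(presence)
  if (nrow(M) > 0) {
    M <- M[order(rownames(M)), order(colnames(M)), drop = FALSE]
  }
  genomes <- colnames(M)
  n_gene <- nrow(M)

  if (n_gene == 0) {
    return(new_gene_partition(
      assignment = tibble(gene = character(0), assignment = character(0),
                          loglik_core = numeric(0),
                          loglik_accessory = numeric(0)),
      n_iterations = 0L, converged = TRUE, carriage = NULL,
      posterior_completeness = NULL, genomes = genomes
    ))
  }
  if (any(rowSums(M) == 0)) {
    abort("presence table contains never-observed genes; a gene absent in all genomes is reported `absent`, not classified (see motu_traits()).")
  }

  c_i <- completeness_vector(completeness, genomes)
  freq <- rowMeans(M)
  is_core <- freq >= mean(c_i)

  carriage_from <- function(is_core) {
    n_acc <- sum(!is_core)
    if (n_acc == 0) {
      rep(eps, length(genomes))
    } else {
      colSums(M[!is_core, , drop = FALSE]) / n_acc
    }
  }

  seen <- character(0)
  history <- list()
  converged <- FALSE
  iter <- 0L
  ll_core <- ll_core_matrix(M, c_i, eps)
  p_i <- carriage_from(is_core)
  ll_acc <- ll_acc_matrix(M, p_i, eps)

  while (iter < max_iter) {
    iter <- iter + 1L
    new_core <- ll_core > ll_acc
    key <- paste(as.integer(new_core), collapse = "")
    if (identical(new_core, is_core)) {
      is_core <- new_core
      converged <- TRUE
      break
    }
    if (key %in% seen) {
      # oscillation: return the lexicographically smallest assignment seen
      # within the cycle
      cycle_keys <- seen[which(seen == key):length(seen)]
      best <- sort(cycle_keys)[1]
      is_core <- history[[best]]
      p_i <- carriage_from(is_core)
      ll_acc <- ll_acc_matrix(M, p_i, eps)
      converged <- FALSE
      break
    }
    seen <- c(seen, key)
    history[[key]] <- new_core
    is_core <- new_core
    if (reestimate_completeness) {
      n_core <- sum(is_core)
      c_i <- if (n_core == 0) rep(eps, length(genomes)) else
        colSums(M[is_core, , drop = FALSE]) / n_core
      ll_core <- ll_core_matrix(M, c_i, eps)
    }
    p_i <- carriage_from(is_core)
    ll_acc <- ll_acc_matrix(M, p_i, eps)
  }
  if (iter == max_iter && !converged) {
    # max_iter exhausted without fixed point or detected cycle
    converged <- FALSE
  }
  # final decision rule, recomputed at the returned state
  new_gene_partition(
    assignment = tibble(
      gene = rownames(M),
      assignment = unname(ifelse(ll_core > ll_acc, "core", "accessory")),
      loglik_core = unname(ll_core),
      loglik_accessory = unname(ll_acc)
    ),
    n_iterations = iter,
    converged = converged,
    carriage = setNames(clamp_prob(p_i, eps), genomes),
    posterior_completeness = if (reestimate_completeness)
      setNames(clamp_prob(c_i, eps), genomes) else NULL,
    genomes = genomes
  )
}

new_gene_partition <- function(assignment, n_iterations, converged, carriage,
                               posterior_completeness, genomes) {
  structure(
    list(assignment = assignment, n_iterations = n_iterations,
         converged = converged, carriage = carriage,
         posterior_completeness = posterior_completeness,
         genomes = genomes),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(
    "<gene_partition> %d genes over %d genomes: %d core / %d accessory (%s in %d iteration%s)\n",
    nrow(x$assignment), length(x$genomes),
    sum(x$assignment$assignment == "core"),
    sum(x$assignment$assignment == "accessory"),
    if (x$converged) "converged" else "not converged",
    x$n_iterations, if (x$n_iterations == 1) "" else "s"
  ))
  invisible(x)
}

#' Per-gene tidy view of a gene partition
#'
#' @param x a `gene_partition` from [classify_genes()].
#' @param ... unused.
#' @return tibble (gene, assignment, loglik_core, loglik_accessory).
#' @exportS3Method generics::tidy
tidy.gene_partition <- function(x, ...) x$assignment

#' One-row summary of a gene partition
#'
#' @param x a `gene_partition`.
#' @param ... unused.
#' @return tibble (n_genes, n_core, n_accessory, n_iterations, converged,
#'   mean_posterior_completeness).
#' @exportS3Method generics::glance
glance.gene_partition <- function(x, ...) {
  tibble(
    n_genes = nrow(x$assignment),
    n_core = sum(x$assignment$assignment == "core"),
    n_accessory = sum(x$assignment$assignment == "accessory"),
    n_iterations = x$n_iterations,
    converged = x$converged,
    mean_posterior_completeness =
      if (is.null(x$posterior_completeness)) NA_real_
      else mean(x$posterior_completeness)
  )
}

#' Summarize one or many gene partitions
#'
#' @param partition a `gene_partition` or a named list of them (one per
#'   mOTU).
#' @return tibble with one row per partition (motu_id column when a named
#'   list is given).
#' @export
summarize_partition <- function(partition) {
  if (inherits(partition, "gene_partition")) return(glance(partition))
  stopifnot(is.list(partition))
  bind_rows(lapply(partition, glance), .id = "motu_id")
}

#' Classify genes mOTU-by-mOTU
#'
#' Convenience driver: splits a combined observed gene-content table by
#' mOTU (using a [cluster_motus()] catalog) and runs [classify_genes()] on
#' each mOTU's member genomes.
#'
#' @param gene_content long tibble (genome_id, gene) of observed gene
#'   clusters.
#' @param catalog a `motu_catalog`.
#' @param completeness completeness per genome (named vector, fraction or
#'   percent, or metadata data frame).
#' @param ... passed to [classify_genes()].
#' @return named list of `gene_partition` objects, one per mOTU.
#' @export
classify_by_motu <- function(gene_content, catalog, completeness, ...) {
  members <- as_tibble(catalog) |> filter(!is.na(.data$motu_id))
  motus <- sort(unique(members$motu_id))
  out <- lapply(motus, function(m) {
    ids <- members$genome_id[members$motu_id == m]
    pres <- presence_matrix(
      gene_content |> filter(.data$genome_id %in% ids), genomes = ids)
    classify_genes(pres, completeness, ...)
  })
  setNames(out, motus)
}

#' Plot the likelihood landscape of a gene partition
#'
#' Observed gene frequency against the core-vs-accessory log-likelihood
#' margin, colored by the final assignment.
#'
#' @param object a `gene_partition`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_partition <- function(object, ...) {
  df <- object$assignment |>
    mutate(margin = .data$loglik_core - .data$loglik_accessory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$margin,
                                   fill = .data$assignment)) +
    ggplot2::geom_histogram(bins = 50, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log-likelihood margin (core - accessory)",
                  y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
}
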