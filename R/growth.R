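# Genome-composition simulation: pan-, core- and soft-core-genome growth
# over random accession orderings, and exponential-saturation fits.

#' Simulate pan/core/soft-core genome growth over random accession orders
#'
#' For each seeded permutation the sequence pool starts with the first
#' accession's non-redundant sequences. At step n, a sequence of accession
#' n is *novel* iff no pool sequence matches it with identity >=
#' `novel_identity` and shortest-mode coverage >= `novel_coverage`
#' (defaults 70 / 50: permissive enough for retained/unprocessed introns).
#' pan(n) is the pool size after adding novelties; core(n) counts pool
#' sequences with a qualifying match in every accession seen so far;
#' soft_core(n) counts pool sequences matched in at least
#' `ceil(soft_fraction * n)` of them. Matching is sequence-level (not via
#' clusters), with the query being the incoming sequence and coverage over
#' the shortest sequence.
#'
#' @param seqs `accession_set` (>= 2 accessions).
#' @param graph optional `similarity_graph`. The growth thresholds are
#'   applied to its stored merged pairs; when omitted, all-vs-all hits are
#'   computed with the built-in aligner (HSP identity floor
#'   `novel_identity`).
#' @param permutations number of random accession orderings, default 20.
#' @param novel_identity,novel_coverage novelty-match thresholds
#'   (defaults 70 / 50, inclusive).
#' @param soft_fraction soft-core fraction, default 0.95.
#' @param seed RNG seed for the permutations.
#' @return `growth_curves`: list with matrices `pan`, `core`, `soft_core`
#'   (permutations x n), the permutation orders, and the parameters used.
#' @export
simulate_composition <- function(seqs, graph = NULL, permutations = 20L,
                                 novel_identity = 70, novel_coverage = 50,
                                 soft_fraction = 0.95, seed = 1L) {
  accs <- seqs$accessions
  n_acc <- length(accs)
  if (n_acc < 2L) stopf("growth simulation needs at least 2 accessions")
  if (is.null(graph)) {
    hsps <- compute_all_hits(seqs, min_hsp_identity = min(novel_identity, 90))
    graph <- build_similarity_graph(hsps, seqs, min_identity = novel_identity,
                                    min_coverage = novel_coverage)
  }
  ids <- seqs$records$seq_id
  acc_of <- setNames(seqs$records$accession, ids)
  # symmetric qualifying-match adjacency at the novelty thresholds
  p <- graph$pairs
  qualify <- p$identity >= novel_identity & p$coverage >= novel_coverage
  qp <- p[qualify, , drop = FALSE]
  nbr <- split(c(qp$s_id, qp$q_id), c(qp$q_id, qp$s_id))
  nbr <- lapply(nbr, unique)
  # accessions reachable from each sequence through a qualifying match
  acc_sets <- lapply(ids, function(x) unique(c(acc_of[[x]], acc_of[nbr[[x]]])))
  names(acc_sets) <- ids
  by_acc <- split(ids, acc_of[ids])

  # non-redundant subset of one accession under the novelty rule:
  # greedy by descending length, drop sequences matching a kept one
  nr_of_acc <- lapply(by_acc, function(aids) {
    aids <- aids[order(-seq_length(seqs, aids), aids)]
    kept <- character(0)
    for (x in aids) {
      if (!any(nbr[[x]] %in% kept)) kept <- c(kept, x)
    }
    kept
  })

  pan <- core <- soft <- matrix(
    0L, permutations, n_acc,
    dimnames = list(NULL, paste0("n", seq_len(n_acc))))
  orders <- with_seed(seed, replicate(permutations, sample(accs), simplify = FALSE))
  for (pi in seq_len(permutations)) {
    ord <- orders[[pi]]
    pool <- nr_of_acc[[ord[1L]]]
    pan[pi, 1L] <- length(pool)
    core[pi, 1L] <- length(pool)
    soft[pi, 1L] <- length(pool)
    for (n in 2:n_acc) {
      incoming <- nr_of_acc[[ord[n]]]
      pool_set <- structure(rep(TRUE, length(pool)), names = pool)
      novel <- incoming[!vapply(incoming, function(x)
        any(!is.na(pool_set[nbr[[x]]])), TRUE)]
      pool <- c(pool, novel)
      seen <- ord[seq_len(n)]
      n_match <- vapply(pool, function(x) sum(seen %in% acc_sets[[x]]), 0L)
      pan[pi, n] <- length(pool)
      core[pi, n] <- sum(n_match == n)
      soft[pi, n] <- sum(n_match >= ceiling(soft_fraction * n))
    }
  }
  structure(
    list(pan = pan, core = core, soft_core = soft, orders = orders,
         permutations = permutations, seed = seed,
         novel_identity = novel_identity, novel_coverage = novel_coverage,
         soft_fraction = soft_fraction),
    class = "growth_curves"
  )
}

#' @export
print.growth_curves <- function(x, ...) {
  n <- ncol(x$pan)
  cat(sprintf(
    "growth_curves: %d permutations x %d accessions; mean pan(%d) = %.1f, mean core(%d) = %.1f\n",
    x$permutations, n, n, mean(x$pan[, n]), n, mean(x$core[, n])))
  invisible(x)
}

#' Write growth curves as per-kind TSV files
#' @param curves `growth_curves`.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_growth_curves <- function(curves, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("pan", "core", "soft_core"), function(kind) {
    df <- data.frame(permutation = seq_len(nrow(curves[[kind]])),
                     curves[[kind]], check.names = FALSE)
    write_tsv(df, file.path(outdir, paste0(kind, "_genome.tsv")))
  }, "")
  invisible(paths)
}

# kappa * exp(-n / tau) + omega fitted by multi-start nonlinear least squares
fit_exp_decay <- function(n, y) {
  if (length(unique(y)) == 1L) {
    return(list(kappa = 0, tau = 1, omega = y[1L], sse = 0, degenerate = TRUE))
  }
  n_max <- max(n)
  last_vals <- y[n == n_max]
  omega0 <- c(mean(last_vals), mean(y[n >= sort(unique(n), decreasing = TRUE)[min(3L, length(unique(n)))]]))
  tau0 <- c(1, n_max / 3)
  best <- NULL
  for (o0 in omega0) {
    for (t0 in tau0) {
      k0 <- mean(y[n == min(n)]) - o0
      if (k0 == 0) k0 <- max(abs(y - o0), 1)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ kappa * exp(-n / tau) + omega,
          start = list(kappa = k0, tau = t0, omega = o0),
          lower = c(-Inf, 1e-6, 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        cf <- coef(fit)
        best <- list(kappa = unname(cf["kappa"]), tau = unname(cf["tau"]),
                     omega = unname(cf["omega"]), sse = sse, degenerate = FALSE)
      }
    }
  }
  if (is.null(best)) {
    # flat fallback: decay to the mean
    best <- list(kappa = 0, tau = 1, omega = mean(y), sse = sum((y - mean(y))^2),
                 degenerate = TRUE)
  }
  best
}

#' Fit an exponential-saturation model to growth curves
#'
#' The core (or soft-core) curve is fitted directly as
#' `core(n) = kappa * exp(-n/tau) + omega` on all permutation points. The
#' pan curve is fitted on per-step novel-gene counts
#' `novel(n) = pan(n) - pan(n-1)` for n >= 2 (same model; `omega` is then
#' the asymptotic number of novel genes contributed per added genome), and
#' the fitted pan curve is reconstructed by cumulative summation from
#' pan(1). Multi-start initialization makes the fit robust to the usual
#' initialization sensitivity of exponential models.
#'
#' @param curves `growth_curves`.
#' @param kind `"core"`, `"soft_core"` or `"pan"`.
#' @param model only `"exp_decay"` is implemented.
#' @return `growth_fit`: list with `kappa`, `tau`, `omega`, `residual_sse`,
#'   `model_name`, `kind` (and `pan1` for the pan fit).
#' @export
fit_growth <- function(curves, kind = c("core", "soft_core", "pan"),
                       model = c("exp_decay")) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  mat <- curves[[kind]]
  n_acc <- ncol(mat)
  if (kind == "pan") {
    if (n_acc < 5L) stopf("need at least 4 distinct n values for the fit")
    novel <- mat[, -1L, drop = FALSE] - mat[, -n_acc, drop = FALSE]
    n <- rep(2:n_acc, each = nrow(mat))
    y <- as.vector(novel)
  } else {
    if (n_acc < 4L) stopf("need at least 4 distinct n values for the fit")
    n <- rep(seq_len(n_acc), each = nrow(mat))
    y <- as.vector(mat)
  }
  f <- fit_exp_decay(n, y)
  structure(
    list(kappa = f$kappa, tau = f$tau, omega = f$omega,
         residual_sse = f$sse, model_name = model, kind = kind,
         degenerate = f$degenerate,
         pan1 = if (kind == "pan") mean(mat[, 1L]) else NULL),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit [%s, %s]: kappa=%.4g, tau=%.4g, omega=%.4g (SSE %.4g)\n",
              x$kind, x$model_name, x$kappa, x$tau, x$omega, x$residual_sse))
  invisible(x)
}

#' Predict a fitted growth curve
#'
#' @param object `growth_fit`.
#' @param n vector of genome counts.
#' @param ... unused.
#' @return predicted curve values; for the pan fit, cumulative from pan(1).
#' @export
predict.growth_fit <- function(object, n, ...) {
  g <- function(nn) object$kappa * exp(-nn / object$tau) + object$omega
  if (object$kind != "pan") return(g(n))
  vapply(n, function(nn) {
    if (nn <= 1L) return(object$pan1)
    object$pan1 + sum(g(2:nn))
  }, 0)
}

#' Summarize growth curves and fits
#'
#' Reports the smallest number of genomes n* at which the mean pan curve
#' reaches `coverage_target` (default 99%) of its final mean size, the
#' asymptotic number of novel genes per added genome (omega of the pan
#' fit), and the mean and SD of the final pan size across permutations.
#'
#' @param curves `growth_curves`.
#' @param fits optional named list of `growth_fit` objects (`pan`, `core`);
#'   computed when missing.
#' @param coverage_target fraction of the final pan size, default 0.99.
#' @return one-row data.frame.
#' @export
growth_summary <- function(curves, fits = NULL, coverage_target = 0.99) {
  if (is.null(fits)) {
    fits <- list(pan = fit_growth(curves, "pan"),
                 core = fit_growth(curves, "core"))
  }
  mean_pan <- colMeans(curves$pan)
  n_acc <- length(mean_pan)
  n_star <- which(mean_pan >= coverage_target * mean_pan[n_acc])[1L]
  data.frame(
    n_genomes = n_acc,
    permutations = curves$permutations,
    n_saturation = n_star,
    coverage_target = coverage_target,
    novel_per_genome = fits$pan$omega,
    core_asymptote = fits$core$omega,
    pan_final_mean = mean(curves$pan[, n_acc]),
    pan_final_sd = stats::sd(curves$pan[, n_acc]),
    core_final_mean = mean(curves$core[, n_acc])
  )
}
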