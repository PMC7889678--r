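#' Configuration for the synthetic paired-panel generator
#'
#' Defines the geometry and noise model of a simulated targeted expression
#' study: a custom panel of endogenous genes (default 201), candidate
#' reference genes (default 6), negative and positive control probes, and
#' paired baseline/progression biopsies from `n_pairs` patients (default 29,
#' giving 58 samples). Co-expression structure is planted as latent factors:
#' genes of module `m` share a per-sample factor with gene-specific loadings,
#' and the first module's factor is shifted by `-delta` (in factor SD units)
#' in progression samples, emulating a treatment-reduced immune module.
#'
#' @param n_endogenous number of endogenous panel genes.
#' @param n_norm_candidates number of candidate reference genes.
#' @param n_neg_controls number of negative-control (orphan) probes.
#' @param n_pos_controls number of positive-control ladder probes.
#' @param n_pairs number of patients, each with one baseline and one
#'   progression sample.
#' @param module_sizes integer vector of planted module sizes; must sum to at
#'   most `n_endogenous`. Remaining genes are unassigned background.
#' @param loading_range length-2 numeric in (0, 1]: factor loadings of module
#'   genes are drawn uniformly from this interval.
#' @param delta non-negative shift (factor SD units) applied to module 1's
#'   latent factor in progression samples. `delta = 0` makes the two
#'   timepoints exchangeable for module 1.
#' @param noise_sd residual SD on the log2 expression scale. The default
#'   0.15 matches technical replication noise of counting panels (CV around
#'   10 percent) and keeps within-module correlations high enough that the
#'   planted structure is detectable at the standard signed-network settings
#'   (see the vignette).
#' @param neg_control_rate expected negative-control count (Poisson mean).
#' @param unstable_candidates how many of the candidate reference genes get
#'   3x `noise_sd` (emulating unstable housekeeping genes geNorm should
#'   reject); at most `n_norm_candidates`.
#' @param seed integer seed; identical configurations give bit-identical
#'   datasets.
#' @return An object of class `simulation_config` (validated list).
#' @seealso [simulate_panel()], [simulate_gene_sets()]
#' @export
simulation_config <- function(n_endogenous = 201L,
                              n_norm_candidates = 6L,
                              n_neg_controls = 8L,
                              n_pos_controls = 6L,
                              n_pairs = 29L,
                              module_sizes = c(47L, 30L, 25L, 20L),
                              loading_range = c(0.5, 0.9),
                              delta = 0.8,
                              noise_sd = 0.15,
                              neg_control_rate = 10,
                              unstable_candidates = 2L,
                              seed = 1L) {
  counts <- c(n_endogenous = n_endogenous, n_norm_candidates = n_norm_candidates,
              n_neg_controls = n_neg_controls, n_pos_controls = n_pos_controls,
              n_pairs = n_pairs, unstable_candidates = unstable_candidates)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count parameters must be non-negative integers")
  if (any(module_sizes <= 0) || any(module_sizes != round(module_sizes)))
    stop("`module_sizes` must be positive integers")
  if (sum(module_sizes) > n_endogenous)
    stop("sum(module_sizes) exceeds n_endogenous: configuration error")
  if (length(loading_range) != 2 || any(loading_range <= 0) ||
      any(loading_range > 1) || loading_range[1] > loading_range[2])
    stop("`loading_range` must be an increasing pair in (0, 1]")
  if (delta < 0) stop("`delta` must be >= 0")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (neg_control_rate <= 0) stop("`neg_control_rate` must be > 0")
  if (unstable_candidates > n_norm_candidates)
    stop("`unstable_candidates` exceeds n_norm_candidates")
  if (n_pairs < 1) stop("need at least one patient pair")
  structure(list(n_endogenous = as.integer(n_endogenous),
                 n_norm_candidates = as.integer(n_norm_candidates),
                 n_neg_controls = as.integer(n_neg_controls),
                 n_pos_controls = as.integer(n_pos_controls),
                 n_pairs = as.integer(n_pairs),
                 module_sizes = as.integer(module_sizes),
                 loading_range = as.numeric(loading_range),
                 delta = as.numeric(delta),
                 noise_sd = as.numeric(noise_sd),
                 neg_control_rate = as.numeric(neg_control_rate),
                 unstable_candidates = as.integer(unstable_candidates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$n_endogenous, "endogenous genes,",
      x$n_pairs, "patient pairs\n")
  cat("  planted modules:", paste(x$module_sizes, collapse = "/"),
      " delta =", x$delta, " noise_sd =", x$noise_sd,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate a paired targeted expression dataset with planted modules
#'
#' Generates probe-level counts for a paired baseline/progression design.
#' For each planted module `m` and sample `s` a latent factor
#' `f[m, s] ~ N(0, 1)` is drawn; progression samples of module 1 have mean
#' `-delta`. Endogenous log2 expression is
#' `mu_g + lambda_g * f[m(g), s] + eps`, with gene baselines `mu_g` uniform on
#' \[4, 12\] log2 counts (so detection calls vary across the panel), loadings
#' `lambda_g` uniform on `loading_range` for module genes (0 for background)
#' and `eps ~ N(0, noise_sd)`. Counts are Poisson with mean `2^expression`.
#' Negative controls are Poisson(`neg_control_rate`); positive controls follow
#' a fixed four-fold geometric ladder. Candidate reference genes have no
#' factor loading; `unstable_candidates` of them get 3x `noise_sd`.
#'
#' One designated endogenous gene (`IFNG_SYN`, a synthetic interferon-gamma
#' analogue) belongs to module 1, has a baseline near the detection threshold
#' and carries the maximal loading, so that its detectability tracks the
#' module factor and drops at progression when `delta > 0`.
#'
#' @param config a [simulation_config()].
#' @return A list of class `panel_simulation` with elements
#'   \describe{
#'     \item{counts}{[raw_counts] probe x sample matrix (endogenous,
#'       candidates, negative then positive controls).}
#'     \item{samples}{data.frame with columns `sample`, `patient`,
#'       `timepoint` (`baseline`/`progression`) and `arm` (`CIS+PEM` /
#'       `CIS+PEM+BEV`, in the study's 11:18 pair proportion).}
#'     \item{truth}{ground truth: `module_of_gene` (named vector over
#'       endogenous genes, background = `"unassigned"`),
#'       `stable_reference_genes`, `delta`, `factor_values` (module x sample
#'       matrix), `ifng_gene`, `loadings`, `baselines`.}
#'   }
#' @examples
#' sim <- simulate_panel(simulation_config(seed = 7))
#' dim(sim$counts)
#' table(sim$truth$module_of_gene)
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    cfg <- config
    n_mod <- length(cfg$module_sizes)
    n_s <- 2L * cfg$n_pairs

    patients <- sprintf("P%02d", seq_len(cfg$n_pairs))
    sample_ids <- as.vector(rbind(paste0(patients, "_BL"), paste0(patients, "_PG")))
    timepoint <- rep(c("baseline", "progression"), cfg$n_pairs)
    n_cispem <- round(cfg$n_pairs * 11 / 29)
    arm_of_patient <- rep(c("CIS+PEM", "CIS+PEM+BEV"),
                          c(n_cispem, cfg$n_pairs - n_cispem))
    samples <- data.frame(sample = sample_ids,
                          patient = rep(patients, each = 2),
                          timepoint = timepoint,
                          arm = rep(arm_of_patient, each = 2),
                          stringsAsFactors = FALSE)

    genes <- sprintf("G%03d", seq_len(cfg$n_endogenous))
    module_of_gene <- rep("unassigned", cfg$n_endogenous)
    mod_index <- rep(NA_integer_, cfg$n_endogenous)
    pos <- 1L
    for (m in seq_len(n_mod)) {
      idx <- pos:(pos + cfg$module_sizes[m] - 1L)
      module_of_gene[idx] <- paste0("M", m)
      mod_index[idx] <- m
      pos <- pos + cfg$module_sizes[m]
    }
    # IFNG analogue: last gene of module 1, low abundance, maximal loading
    ifng_i <- cfg$module_sizes[1]
    genes[ifng_i] <- "IFNG_SYN"
    names(module_of_gene) <- genes
    names(mod_index) <- genes

    mu <- stats::runif(cfg$n_endogenous, 4, 12)
    lambda <- numeric(cfg$n_endogenous)
    in_mod <- !is.na(mod_index)
    lambda[in_mod] <- stats::runif(sum(in_mod),
                                   cfg$loading_range[1], cfg$loading_range[2])
    # baseline near the detection threshold (neg mean + 2 SD ~ log2 16 counts)
    mu[ifng_i] <- log2(cfg$neg_control_rate + 2 * sqrt(cfg$neg_control_rate)) + 0.3
    lambda[ifng_i] <- cfg$loading_range[2]
    names(mu) <- names(lambda) <- genes

    f <- matrix(stats::rnorm(n_mod * n_s), n_mod, n_s,
                dimnames = list(paste0("M", seq_len(n_mod)), sample_ids))
    f[1, timepoint == "progression"] <- f[1, timepoint == "progression"] - cfg$delta

    expr <- mu + matrix(stats::rnorm(cfg$n_endogenous * n_s, 0, cfg$noise_sd),
                        cfg$n_endogenous, n_s)
    for (m in seq_len(n_mod)) {
      idx <- which(mod_index == m)
      expr[idx, ] <- expr[idx, ] + outer(lambda[idx], f[m, ])
    }
    endo_counts <- matrix(stats::rpois(length(expr), 2^expr),
                          cfg$n_endogenous, n_s,
                          dimnames = list(genes, sample_ids))

    hk_ids <- sprintf("HK%02d", seq_len(cfg$n_norm_candidates))
    hk_mu <- stats::runif(cfg$n_norm_candidates, 8, 11)
    hk_sd <- rep(cfg$noise_sd, cfg$n_norm_candidates)
    unstable <- character(0)
    if (cfg$unstable_candidates > 0) {
      take <- seq(cfg$n_norm_candidates - cfg$unstable_candidates + 1L,
                  cfg$n_norm_candidates)
      hk_sd[take] <- 3 * cfg$noise_sd
      unstable <- hk_ids[take]
    }
    hk_expr <- hk_mu + matrix(stats::rnorm(cfg$n_norm_candidates * n_s),
                              cfg$n_norm_candidates, n_s) * hk_sd
    hk_counts <- matrix(stats::rpois(length(hk_expr), 2^hk_expr),
                        cfg$n_norm_candidates, n_s,
                        dimnames = list(hk_ids, sample_ids))

    neg_ids <- sprintf("NEG%02d", seq_len(cfg$n_neg_controls))
    neg_counts <- matrix(stats::rpois(cfg$n_neg_controls * n_s, cfg$neg_control_rate),
                         cfg$n_neg_controls, n_s,
                         dimnames = list(neg_ids, sample_ids))

    pos_ids <- sprintf("POS%02d", seq_len(cfg$n_pos_controls))
    ladder <- 2^15 / 4^(seq_len(cfg$n_pos_controls) - 1L)
    pos_counts <- matrix(stats::rpois(cfg$n_pos_controls * n_s, rep(ladder, n_s)),
                         cfg$n_pos_controls, n_s,
                         dimnames = list(pos_ids, sample_ids))

    values <- rbind(endo_counts, hk_counts, neg_counts, pos_counts)
    storage.mode(values) <- "double"
    probe_class <- stats::setNames(
      rep(c("endogenous", "norm_candidate", "negative", "positive"),
          c(cfg$n_endogenous, cfg$n_norm_candidates,
            cfg$n_neg_controls, cfg$n_pos_controls)),
      rownames(values))

    truth <- list(module_of_gene = module_of_gene,
                  stable_reference_genes = setdiff(hk_ids, unstable),
                  delta = cfg$delta,
                  factor_values = f,
                  ifng_gene = "IFNG_SYN",
                  loadings = lambda,
                  baselines = mu)

    structure(list(counts = raw_counts(values, probe_class),
                   samples = samples,
                   truth = truth,
                   config = cfg),
              class = "panel_simulation")
  })
}

#' @export
print.panel_simulation <- function(x, ...) {
  cat("Synthetic paired panel dataset\n")
  print(x$counts)
  cat("  ", x$config$n_pairs, "patient pairs; planted modules:",
      paste(x$config$module_sizes, collapse = "/"),
      "; delta =", x$config$delta, "\n")
  invisible(x)
}

#' Simulate a gene-set annotation matched to planted modules
#'
#' Builds a synthetic annotation (GMT-style collection) in which each planted
#' module has one enriched term (60% of the term's genes drawn from that
#' module, the rest uniformly from outside it) and any remaining terms are
#' decoys drawn uniformly from the whole panel. With `n_terms = 0` an empty
#' collection is returned.
#'
#' @param truth the `truth` element of a [simulate_panel()] result (or the
#'   full `panel_simulation`).
#' @param n_terms total number of terms; the first `min(n_terms, n_modules)`
#'   are the planted per-module terms.
#' @param seed integer seed.
#' @return A [gene_set_collection].
#' @export
simulate_gene_sets <- function(truth, n_terms = 12L, seed = 1L) {
  if (inherits(truth, "panel_simulation")) truth <- truth$truth
  stopifnot(is.list(truth), !is.null(truth$module_of_gene))
  if (n_terms < 0 || n_terms != round(n_terms)) stop("`n_terms` must be a count")
  if (n_terms == 0) return(gene_set_collection(list()))
  with_seed(seed, {
    genes <- names(truth$module_of_gene)
    mods <- setdiff(unique(truth$module_of_gene), "unassigned")
    sets <- list(); desc <- character(0)
    n_planted <- min(n_terms, length(mods))
    for (i in seq_len(n_planted)) {
      mg <- genes[truth$module_of_gene == mods[i]]
      k <- min(length(mg), 15L)
      core <- sample(mg, k)
      n_bg <- floor(k * 2 / 3)            # core fraction stays >= 60%
      bg <- sample(setdiff(genes, mg), min(n_bg, length(genes) - length(mg)))
      id <- sprintf("SET_%s", mods[i])
      sets[[id]] <- c(core, bg)
      desc[id] <- sprintf("planted term for module %s", mods[i])
    }
    for (j in seq_len(max(0L, n_terms - n_planted))) {
      s <- sample(10:30, 1)
      id <- sprintf("SET_RND%02d", j)
      sets[[id]] <- sample(genes, min(s, length(genes)))
      desc[id] <- "decoy term"
    }
    gene_set_collection(sets, desc)
  })
}
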