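# Synthetic multi-site connectome generator with planted ground truth.
#
# The generator emulates the structure of a multi-site autism resting-state
# cohort: a model sample and an independent validation sample of patients
# whose behavioural score is coupled (negatively, by default) to a sparse
# planted edge set, plus a small control sample with healthy-range scores
# and NO edge-behaviour coupling.  Covariates (age, sex, motion) are
# partially correlated with the behaviour, and each site contributes
# additive and multiplicative edge effects drawn from the
# Gaussian/inverse-gamma family assumed by empirical-Bayes harmonization.

#' Specification for the synthetic multi-site generator
#'
#' Defaults reproduce the cohort structure of the emulated study: 151
#' model-sample patients, 172 validation-sample patients, and 36 controls
#' on a 160-node, six-network connectome; behavioural scores use ADOS-like
#' means/SDs (total 11.9 +/- 4.0 in the model sample, 1.3 +/- 1.7 in
#' controls); 40 planted negative edges with effect size `beta = 1.5`
#' z-units per behaviour SD against unit edge noise.
#'
#' @param n_model,n_validation,n_control Sample sizes.
#' @param n_nodes Connectome size `N`.
#' @param true_edges Planted edge set: data frame / matrix with columns
#'   `i`, `j` (`i < j`) and `sign` (+1/-1), or `NULL` to draw
#'   `n_true_neg` + `n_true_pos` edges at generation time.
#' @param n_true_neg,n_true_pos Number of planted negative / positive
#'   edges when `true_edges` is `NULL`.
#' @param beta Planted effect size: z-units of edge weight per SD of
#'   behaviour.
#' @param noise_sd SD of per-edge noise (z-units).
#' @param edge_mu_mean,edge_mu_sd Distribution of per-edge baseline
#'   weights.
#' @param covariate_effects Named vector of slopes (in behaviour-SD units
#'   per covariate SD) for `age`, `sex`, `mfd` on the latent behaviour.
#' @param score_means,score_sds Named lists (`model`, `validation`,
#'   `control`) of length-4 vectors (total, social, communication, rrb)
#'   giving score distribution parameters per sample.
#' @param n_sites_model,n_sites_validation,n_sites_control Site counts.
#' @param site_gamma_sd SD of per-site mean additive offsets (z-units);
#'   0 disables additive site effects.
#' @param site_gamma_tau SD of per-edge additive offsets around the site
#'   mean.
#' @param site_delta_log_sd SD of log per-site noise-scale factors; 0
#'   disables multiplicative site effects.
#' @param site_delta_shape Shape of the inverse-gamma spread of per-edge
#'   variance scales around the site scale (larger = tighter).
#' @param subtype_probs Probabilities for patient subtypes CA / AS /
#'   PDD-NOS.
#' @return A list of class `cpm_generator_spec`.
#' @export
generator_spec <- function(n_model = 151, n_validation = 172, n_control = 36,
                           n_nodes = 160,
                           true_edges = NULL, n_true_neg = 40, n_true_pos = 0,
                           beta = 1.5, noise_sd = 1,
                           edge_mu_mean = 0.25, edge_mu_sd = 0.15,
                           covariate_effects = c(age = 0.2, sex = 0.1, mfd = 0.3),
                           score_means = list(
                             model = c(total = 11.89, social = 8.12,
                                       communication = 3.93, rrb = 2.10),
                             validation = c(total = 10.38, social = 7.05,
                                            communication = 3.08, rrb = 1.71),
                             control = c(total = 1.33, social = 0.67,
                                         communication = 0.67, rrb = 0.03)),
                           score_sds = list(
                             model = c(total = 4.00, social = 2.94,
                                       communication = 1.62, rrb = 1.78),
                             validation = c(total = 3.91, social = 2.59,
                                            communication = 1.50, rrb = 1.38),
                             control = c(total = 1.66, social = 0.96,
                                         communication = 1.01, rrb = 0.67)),
                           n_sites_model = 5, n_sites_validation = 5,
                           n_sites_control = 2,
                           site_gamma_sd = 0.15, site_gamma_tau = 0.05,
                           site_delta_log_sd = 0.15, site_delta_shape = 51,
                           subtype_probs = c(CA = 0.70, AS = 0.20,
                                             `PDD-NOS` = 0.10)) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (site_delta_log_sd < 0 || site_gamma_sd < 0) stop("site-effect SDs must be >= 0")
  if (!is.null(true_edges)) {
    true_edges <- as.data.frame(true_edges)
    stopifnot(all(c("i", "j", "sign") %in% names(true_edges)))
    if (any(true_edges$i >= true_edges$j) || any(true_edges$i < 1) ||
        any(true_edges$j > n_nodes)) {
      stop("true edges must satisfy 1 <= i < j <= n_nodes")
    }
    if (!all(true_edges$sign %in% c(-1, 1))) stop("true edge sign must be +1 or -1")
  }
  structure(as.list(environment()), class = "cpm_generator_spec")
}

# Seed substreams: one global seed, fixed offsets per component, in this
# order: +1 truth (planted edges, baselines), +2 site effects, +3 phenotype,
# +4 edge noise, +5 time series.  Keeps every derived seed a valid 32-bit
# integer for small global seeds.
substream <- function(seed, k) as.integer(seed + k)

#' Generate a synthetic multi-site dataset
#'
#' Behaviour is generated first (baseline + covariate effects + noise),
#' then edges: planted edges add `sign * beta * standardize(score)` on top
#' of their baseline; every edge receives its site's additive offset and
#' scale-inflated noise.  Control subjects draw scores from the
#' healthy-range distribution and receive no edge-behaviour coupling, so
#' specificity tests are null by construction.  Identical `(spec, seed)`
#' yield bit-identical datasets.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed driving all substreams.
#' @return A list of class `cpm_synth` with `edges` (subjects x E matrix,
#'   canonical edge order, subject ids as rownames), `pheno` (phenotype
#'   data frame incl. `sample`, `site`, covariates, scores, QC columns),
#'   `atlas`, and `truth` (planted edges, per-subject latent behaviour,
#'   site parameters, spec echo).
#' @export
generate <- function(spec, seed) {
  stopifnot(inherits(spec, "cpm_generator_spec"))
  N <- spec$n_nodes
  E <- n_edges(N)

  ## -- truth substream: planted edges and edge baselines
  set.seed(substream(seed, 1))
  if (is.null(spec$true_edges)) {
    n_true <- spec$n_true_neg + spec$n_true_pos
    pos <- sample.int(E, n_true)
    idx <- edge_index(N)
    true_edges <- data.frame(i = idx[pos, 1], j = idx[pos, 2],
                             sign = rep(c(-1L, 1L),
                                        c(spec$n_true_neg, spec$n_true_pos)))
  } else {
    true_edges <- spec$true_edges
  }
  true_pos <- edge_position(true_edges$i, true_edges$j, N)
  mu <- stats::rnorm(E, spec$edge_mu_mean, spec$edge_mu_sd)

  ## -- site-effect substream
  set.seed(substream(seed, 2))
  sites <- c(paste0("I_", seq_len(spec$n_sites_model)),
             paste0("II_", seq_len(spec$n_sites_validation)),
             paste0("HC_", seq_len(spec$n_sites_control)))
  site_par <- lapply(sites, function(s) {
    g_mean <- stats::rnorm(1, 0, spec$site_gamma_sd)
    gamma <- if (spec$site_gamma_sd > 0 || spec$site_gamma_tau > 0)
      stats::rnorm(E, g_mean, spec$site_gamma_tau) else numeric(E)
    d_site <- exp(stats::rnorm(1, 0, spec$site_delta_log_sd))
    delta <- if (spec$site_delta_log_sd > 0) {
      a <- spec$site_delta_shape
      sqrt((a - 1) * d_site^2 / stats::rgamma(E, shape = a, rate = 1))
    } else rep(1, E)
    list(gamma = gamma, delta = delta, g_mean = g_mean, d_site = d_site)
  })
  names(site_par) <- sites

  ## -- phenotype substream
  set.seed(substream(seed, 3))
  samples <- rep(c("model", "validation", "control"),
                 c(spec$n_model, spec$n_validation, spec$n_control))
  n_tot <- length(samples)
  ids <- sprintf("S%04d", seq_len(n_tot))
  age <- stats::runif(n_tot, 7, 40)
  sex <- ifelse(stats::runif(n_tot) < 0.92, "M", "F")
  mfd <- stats::rlnorm(n_tot, log(0.085), 0.4)
  fiq <- stats::rnorm(n_tot, 105, 15)
  site <- character(n_tot)
  for (sm in c("model", "validation", "control")) {
    k <- switch(sm, model = spec$n_sites_model,
                validation = spec$n_sites_validation,
                control = spec$n_sites_control)
    pool <- switch(sm, model = paste0("I_", seq_len(k)),
                   validation = paste0("II_", seq_len(k)),
                   control = paste0("HC_", seq_len(k)))
    site[samples == sm] <- sample(pool, sum(samples == sm), replace = TRUE)
  }
  subtype <- ifelse(samples == "control", "HC",
                    sample(names(spec$subtype_probs), n_tot, replace = TRUE,
                           prob = spec$subtype_probs))
  eff <- spec$covariate_effects
  lin <- eff[["age"]] * scale_vec(age) + eff[["sex"]] * scale_vec(sex == "M") +
    eff[["mfd"]] * scale_vec(mfd)
  resid_sd <- sqrt(max(1 - sum(eff^2), 0.1))
  latent <- as.numeric(lin + stats::rnorm(n_tot, 0, resid_sd))
  score <- matrix(NA_real_, n_tot, 4,
                  dimnames = list(NULL, c("total", "social", "communication",
                                          "rrb")))
  w_sub <- 0.8  # latent loading of subscores
  for (sm in c("model", "validation", "control")) {
    rows <- samples == sm
    mns <- spec$score_means[[sm]]; sds <- spec$score_sds[[sm]]
    lat_s <- if (sm == "control") stats::rnorm(sum(rows)) else latent[rows]
    if (sm == "control") latent[rows] <- lat_s
    score[rows, "total"] <- mns[["total"]] + sds[["total"]] * lat_s
    for (sub in c("social", "communication", "rrb")) {
      mix <- w_sub * lat_s + sqrt(1 - w_sub^2) * stats::rnorm(sum(rows))
      score[rows, sub] <- mns[[sub]] + sds[[sub]] * mix
    }
  }
  score <- pmax(score, 0)
  pheno <- data.frame(
    subject_id = ids, sample = samples,
    group = ifelse(samples == "control", "control", "patient"),
    subtype = subtype, site = site,
    score_total = score[, "total"], score_social = score[, "social"],
    score_communication = score[, "communication"], score_rrb = score[, "rrb"],
    age = age, sex = sex, mfd = mfd, fiq = fiq,
    handedness = "right",
    n_timepoints = sample(150:300, n_tot, replace = TRUE),
    max_motion_mm = stats::runif(n_tot, 0.1, 1.5),
    max_motion_deg = stats::runif(n_tot, 0.1, 1.5),
    stringsAsFactors = FALSE)

  ## -- edge substream
  set.seed(substream(seed, 4))
  edges <- matrix(stats::rnorm(n_tot * E, 0, spec$noise_sd), n_tot, E)
  for (s in seq_len(n_tot)) {
    sp <- site_par[[site[s]]]
    edges[s, ] <- mu + sp$gamma + sp$delta * edges[s, ]
  }
  # couple planted edges to the sample-standardized behaviour (patients only)
  for (sm in c("model", "validation")) {
    rows <- which(samples == sm)
    b_std <- scale_vec(pheno$score_total[rows])
    edges[rows, true_pos] <- edges[rows, true_pos] +
      outer(as.numeric(b_std), spec$beta * true_edges$sign)
  }
  rownames(edges) <- ids

  atlas <- if (N == 160) default_atlas() else synthetic_atlas(N)
  structure(list(edges = edges, pheno = pheno, atlas = atlas,
                 truth = list(true_edges = true_edges,
                              true_positions = true_pos,
                              latent = stats::setNames(latent, ids),
                              site_params = site_par,
                              spec = spec, seed = seed)),
            class = "cpm_synth")
}

scale_vec <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Minimal synthetic atlas for non-standard node counts
#'
#' Assigns `n_nodes` nodes round-robin to `k` generic networks with
#' placeholder coordinates; used for reduced-size simulations.
#'
#' @param n_nodes Number of nodes.
#' @param k Number of networks.
#' @return A `cpm_atlas`.
#' @export
synthetic_atlas <- function(n_nodes, k = 6) {
  k <- min(k, n_nodes)
  as_atlas(data.frame(node_id = seq_len(n_nodes),
                      label = paste0("node_", seq_len(n_nodes)),
                      network = paste0("net", rep_len(seq_len(k), n_nodes)),
                      x = 0, y = 0, z = 0))
}

#' Extract one subject's connectivity matrix from a synthetic dataset
#' @param dataset A `cpm_synth` from [generate()].
#' @param subject_id Subject id (rowname of `dataset$edges`).
#' @return Symmetric `N x N` Fisher-z matrix.
#' @export
subject_connectome <- function(dataset, subject_id) {
  stopifnot(inherits(dataset, "cpm_synth"))
  v <- dataset$edges[subject_id, ]
  devectorize(v, dataset$truth$spec$n_nodes)
}

#' Simulate ROI time series with a prescribed connectome
#'
#' Draws `t_points` i.i.d. Gaussian samples whose population correlation
#' matrix is `tanh(z)` (diagonal 1).  If that matrix is not positive
#' definite it is repaired to the nearest positive-definite matrix
#' (`Matrix::nearPD`) and a message reports the repair; an irreparable
#' target is an error.  [compute_connectome()] applied to the output
#' recovers `z` up to sampling error ~ `1/sqrt(T-3)` per edge.
#'
#' @param z Target symmetric Fisher-z matrix (zero diagonal).
#' @param t_points Number of timepoints `T >= 50`.
#' @return `T x N` numeric matrix.
#' @export
timeseries_from_connectome <- function(z, t_points) {
  validate_connectome(z)
  if (t_points < 50) stop("t_points must be >= 50")
  r <- tanh(z)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    rep <- tryCatch(
      as.matrix(Matrix::nearPD(r, corr = TRUE)$mat),
      error = function(e) stop("target correlation matrix could not be ",
                               "repaired to positive definite: ",
                               conditionMessage(e)))
    message("target correlation repaired to nearest positive definite ",
            "(min eigenvalue was ", format(min(ev), digits = 3), ")")
    r <- rep
  }
  ch <- chol(r)
  matrix(stats::rnorm(t_points * nrow(r)), t_points) %*% ch
}

#' Generate per-subject time series for a synthetic dataset
#'
#' Produces, for each requested subject, a `T x N` series whose population
#' correlation structure matches the subject's generated connectome (see
#' [timeseries_from_connectome()]).
#'
#' @param spec A [generator_spec()] (small `n_nodes` recommended).
#' @param t_points Timepoints per subject.
#' @param seed Integer seed.
#' @param subjects Subject ids to simulate (default: all).
#' @return Named list of `T x N` matrices.
#' @export
generate_timeseries <- function(spec, t_points, seed,
                                subjects = NULL) {
  ds <- generate(spec, seed)
  if (is.null(subjects)) subjects <- rownames(ds$edges)
  set.seed(substream(seed, 5))
  out <- lapply(subjects, function(id) {
    timeseries_from_connectome(subject_connectome(ds, id), t_points)
  })
  names(out) <- subjects
  out
}
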