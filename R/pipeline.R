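# End-to-end study replica: simulate (or load) -> filter -> harmonize ->
# CPM per score and subtype -> external validation -> network anatomy,
# from one configuration, with a run manifest and plain-text log.

#' Pipeline run configuration
#'
#' All knobs of the end-to-end replica in one object.  `seed` is
#' mandatory and drives data generation and every permutation stream, so
#' a rerun with the same configuration is bit-identical.
#'
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory for all stage outputs.
#' @param simulate If `TRUE`, data come from [generate()]; otherwise
#'   `edges_file`/`pheno_file` must point to a [write_edge_table()] /
#'   [write_phenotype()] pair with a `sample` column.
#' @param generator A [generator_spec()] used when `simulate = TRUE`.
#' @param edges_file,pheno_file,atlas_file Input paths when
#'   `simulate = FALSE` (`atlas_file` optional; defaults to the bundled
#'   160-node atlas).
#' @param filter A [filter_config()].
#' @param harmonize Apply site harmonization to each sample.
#' @param combat_mode `"parametric"` or `"nonparametric"`.
#' @param combat_covariates Phenotype columns protected during
#'   harmonization.
#' @param cpm_covariates Phenotype columns used as CPM nuisance
#'   covariates (non-numeric columns are dummy-coded).
#' @param scores Behavioural scores to model (subset of `total`,
#'   `social`, `communication`, `rrb`).
#' @param subtypes Subject subsets to model: `"all"` plus any subtype
#'   levels (e.g. `"CA"`, `"AS"`).
#' @param min_n Minimum subjects for a subset analysis; smaller subsets
#'   are skipped with a logged reason.
#' @param p_threshold Edge-selection threshold.
#' @param n_perm Permutations per model (>= 100).
#' @param tails Tails to model.
#' @return A list of class `cpm_run_config`.
#' @export
run_config <- function(seed,
                       out_dir = "cpm_run",
                       simulate = TRUE,
                       generator = generator_spec(),
                       edges_file = NULL, pheno_file = NULL,
                       atlas_file = NULL,
                       filter = filter_config(),
                       harmonize = TRUE,
                       combat_mode = "parametric",
                       combat_covariates = c("age", "sex", "fiq", "mfd"),
                       cpm_covariates = c("age", "sex", "mfd"),
                       scores = c("total", "social", "communication", "rrb"),
                       subtypes = c("all", "CA", "AS"),
                       min_n = 30,
                       p_threshold = 0.01,
                       n_perm = 1000,
                       tails = c("pos", "neg")) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (!simulate) {
    for (f in c(edges_file, pheno_file, atlas_file)) {
      if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
    }
    if (is.null(edges_file) || is.null(pheno_file)) {
      stop("edges_file and pheno_file are required when simulate = FALSE")
    }
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, generator = generator,
                 edges_file = edges_file, pheno_file = pheno_file,
                 atlas_file = atlas_file, filter = filter,
                 harmonize = harmonize, combat_mode = combat_mode,
                 combat_covariates = combat_covariates,
                 cpm_covariates = cpm_covariates,
                 scores = scores, subtypes = subtypes, min_n = min_n,
                 p_threshold = p_threshold, n_perm = n_perm, tails = tails),
            class = "cpm_run_config")
}

#' Read a run configuration from a plain-text key=value file
#'
#' Lines are `key = value`; `#` starts a comment.  Comma-separated values
#' become vectors; `true`/`false` become logicals; numeric strings become
#' numbers.  Generator fields are prefixed `generator.` and filter fields
#' `filter.` (e.g. `generator.n_model = 60`, `filter.mfd_max = 0.15`).
#'
#' @param path Config file path.
#' @return A `cpm_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    conv <- suppressWarnings(as.numeric(parts))
    out <- if (!anyNA(conv)) conv
           else if (all(tolower(parts) %in% c("true", "false")))
             tolower(parts) == "true"
           else parts
    kv[[key]] <- out
  }
  take_prefix <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(kv), value = TRUE)
    out <- kv[keys]
    names(out) <- sub(paste0("^", prefix, "\\."), "", keys)
    out
  }
  gen <- do.call(generator_spec, take_prefix("generator"))
  fil <- do.call(filter_config, take_prefix("filter"))
  main <- kv[!grepl("^(generator|filter)\\.", names(kv))]
  do.call(run_config, c(main, list(generator = gen, filter = fil)))
}

score_column <- function(score) paste0("score_", score)

# Dummy-code a covariate set into a numeric matrix (first level dropped).
build_covariates <- function(pheno, cols) {
  if (length(cols) == 0) return(NULL)
  miss <- setdiff(cols, names(pheno))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  df <- pheno[cols]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  # a covariate constant within the subset carries no information there
  df <- df[, vapply(df, function(x) length(unique(x)) > 1, logical(1)),
           drop = FALSE]
  if (ncol(df) == 0) return(NULL)
  mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  rownames(mm) <- pheno$subject_id
  mm
}

#' Run the full CPM study replica
#'
#' Executes, in order: data (simulate or load), subject filtering (per
#' sample), site harmonization (each sample harmonized separately), CPM
#' with LOOCV and permutation inference for every requested score x
#' subject-subset combination, transfer of significant-or-not consensus
#' networks to the validation and control samples with family-wise BH-FDR,
#' and network-anatomy summaries.  Every stage writes its tables under
#' `config$out_dir`; a failure aborts with the stage name while retaining
#' partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-model results (`models`),
#'   validation reports (`validation`), summary data frames
#'   (`cpm_summary`, `validation_summary`), and paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cpm_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat("", file = log_path)
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  logln <- function(...) {
    msg <- paste0(...)
    cat(sprintf("[%8.1fs] %s\n", proc.time()[["elapsed"]] - t_start, msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    logln("stage ", name, " started")
    out <- tryCatch(expr, error = function(e) {
      logln("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    logln("stage ", name, " done (", timings[[name]], "s)")
    out
  }

  ## -- data
  dat <- stage("data", {
    if (config$simulate) {
      ds <- generate(config$generator, config$seed)
      write_phenotype(ds$pheno, file.path(config$out_dir, "pheno.csv"))
      list(edges = ds$edges, pheno = ds$pheno, atlas = ds$atlas,
           truth = ds$truth)
    } else {
      edges <- read_edge_table(config$edges_file)
      pheno <- read_phenotype(config$pheno_file)
      atlas <- if (is.null(config$atlas_file)) default_atlas()
               else read_atlas(config$atlas_file)
      if (!"sample" %in% names(pheno)) stop("phenotype needs a 'sample' column")
      pheno <- pheno[match(rownames(edges), pheno$subject_id), , drop = FALSE]
      if (anyNA(pheno$subject_id)) stop("edge table/phenotype subject mismatch")
      list(edges = edges, pheno = pheno, atlas = atlas, truth = NULL)
    }
  })
  n_nodes <- nrow(dat$atlas)

  ## -- filter (per sample; the site-size criterion acts within sample)
  filt <- stage("filter", {
    keep <- character(0)
    excl <- list()
    for (sm in unique(dat$pheno$sample)) {
      sub <- dat$pheno[dat$pheno$sample == sm, , drop = FALSE]
      fc <- config$filter
      # the minimum-site-size rule is a modelling-cohort criterion; the
      # small specificity (control) sample is not subjected to it
      if (sm == "control") fc$min_site_size <- NULL
      fr <- filter_subjects(sub, fc)
      keep <- c(keep, fr$included)
      excl[[sm]] <- fr$excluded
    }
    excl <- do.call(rbind, excl)
    utils::write.csv(excl, file.path(config$out_dir, "excluded_subjects.csv"),
                     row.names = FALSE, quote = FALSE)
    logln("filter: kept ", length(keep), "/", nrow(dat$pheno),
          " subjects (", nrow(excl), " excluded)")
    keep
  })
  pheno <- dat$pheno[dat$pheno$subject_id %in% filt, , drop = FALSE]
  edges <- dat$edges[pheno$subject_id, , drop = FALSE]

  ## -- harmonize each sample separately
  if (config$harmonize) {
    edges <- stage("harmonize", {
      out <- edges
      for (sm in unique(pheno$sample)) {
        rows <- pheno$sample == sm
        covs <- pheno[rows, intersect(config$combat_covariates, names(pheno)),
                      drop = FALSE]
        covs <- covs[, vapply(covs, function(x)
          length(unique(x)) > 1, logical(1)), drop = FALSE]
        h <- combat_fit_transform(edges[rows, , drop = FALSE],
                                  pheno$site[rows],
                                  covariates = if (ncol(covs)) covs else NULL,
                                  mode = config$combat_mode,
                                  allow_singleton_sites = TRUE)
        out[rows, ] <- h$features
        logln("harmonize: sample '", sm, "' over ",
              length(unique(pheno$site[rows])), " site(s), mode ",
              config$combat_mode)
      }
      out
    })
  }

  model_rows <- pheno$sample == "model"
  valid_rows <- pheno$sample == "validation"
  ctrl_rows <- pheno$sample == "control"

  ## -- CPM per subset x score
  models <- list()
  cpm_summary <- NULL
  perm_counter <- 0L
  stage("cpm", {
    for (subset in config$subtypes) {
      rows <- if (subset == "all") model_rows
              else model_rows & pheno$subtype == subset
      for (score in config$scores) {
        col <- score_column(score)
        ok <- rows & !is.na(pheno[[col]])
        n <- sum(ok)
        label <- paste0(subset, "_", score)
        perm_counter <- perm_counter + 1L
        if (n < config$min_n) {
          logln("cpm: skipped ", label, " (n = ", n, " < min_n = ",
                config$min_n, ")")
          next
        }
        cov <- build_covariates(pheno[ok, , drop = FALSE],
                                config$cpm_covariates)
        # one fold sweep serves both the observed LOOCV and its null
        perm <- permutation_test(edges[ok, , drop = FALSE],
                                 pheno[[col]][ok], cov,
                                 config$p_threshold, config$tails,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 100L + perm_counter,
                                 detail = TRUE)
        fit <- perm$observed
        models[[label]] <- list(subset = subset, score = score, n = n,
                                 subjects = pheno$subject_id[ok],
                                 fit = fit, perm = perm)
        for (tail in config$tails) {
          cpm_summary <- rbind(cpm_summary, data.frame(
            model = label, subset = subset, score = score, tail = tail,
            n = n, df = fit$df, r = fit$r[[tail]],
            p_parametric = fit[[paste0("p_parametric_", tail)]],
            p_perm = perm[[tail]]$p_perm,
            mean_null_r = perm[[tail]]$mean_null_r,
            n_consensus = length(fit$consensus[[tail]]),
            empty_folds = fit$empty_folds[[tail]]))
        }
        logln("cpm: ", label, " n = ", n,
              paste0(vapply(config$tails, function(tl) sprintf(
                "; %s r = %.3f p_perm = %.4g (%d consensus)",
                tl, fit$r[[tl]], perm[[tl]]$p_perm,
                length(fit$consensus[[tl]])), character(1)), collapse = ""))
        preds <- data.frame(subject_id = pheno$subject_id[ok],
                            actual = pheno[[col]][ok])
        for (tail in config$tails) {
          preds[[paste0("predicted_", tail)]] <- fit$predictions[[tail]]
        }
        utils::write.csv(preds, file.path(
          config$out_dir, paste0("predictions_", label, ".csv")),
          row.names = FALSE, quote = FALSE)
        write_edge_mask(consensus_mask(fit, n_nodes), file.path(
          config$out_dir, paste0("consensus_", label, ".txt")))
      }
    }
    if (!is.null(cpm_summary)) {
      utils::write.csv(cpm_summary, file.path(config$out_dir,
                                              "cpm_summary.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    NULL
  })

  ## -- external validation & specificity (FDR within each sample family)
  validation <- list()
  validation_summary <- NULL
  if (any(valid_rows) || any(ctrl_rows)) stage("validate", {
    for (label in names(models)) {
      m <- models[[label]]
      col <- score_column(m$score)
      for (tail in config$tails) {
        cons <- m$fit$consensus[[tail]]
        if (length(cons) == 0) {
          logln("validate: ", label, " ", tail,
                " skipped (empty consensus)")
          next
        }
        tm <- transfer_model(edges[m$subjects, , drop = FALSE],
                             pheno[match(m$subjects, pheno$subject_id), col],
                             cons)
        for (sm in c("validation", "control")) {
          rows <- if (sm == "validation") valid_rows else ctrl_rows
          ok <- rows & !is.na(pheno[[col]])
          if (sum(ok) < 10) next
          cov <- build_covariates(pheno[ok, , drop = FALSE],
                                  config$cpm_covariates)
          vr <- external_validate(tm, edges[ok, , drop = FALSE],
                                  pheno[[col]][ok], cov,
                                  sample_label = sm)
          key <- paste0(label, "_", tail, "_", sm)
          validation[[key]] <- vr
          validation_summary <- rbind(validation_summary, data.frame(
            model = label, tail = tail, sample = sm, n = vr$n, df = vr$df,
            r = vr$r, p = vr$p))
        }
      }
    }
    if (!is.null(validation_summary)) {
      validation_summary$p_fdr <- NA_real_
      for (sm in unique(validation_summary$sample)) {
        fam <- validation_summary$sample == sm
        validation_summary$p_fdr[fam] <- fdr_bh(validation_summary$p[fam])
      }
      utils::write.csv(validation_summary,
                       file.path(config$out_dir, "validation_summary.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    NULL
  })

  ## -- anatomy of each consensus network
  stage("anatomy", {
    for (label in names(models)) {
      for (tail in config$tails) {
        cons <- models[[label]]$fit$consensus[[tail]]
        if (length(cons) == 0) next
        mask <- consensus_mask(models[[label]]$fit, n_nodes)
        mask[mask != if (tail == "pos") 1L else -1L] <- 0L
        sm <- summarize_network(mask, dat$atlas)
        write_network_summary(sm, dat$atlas, file.path(
          config$out_dir, paste0("anatomy_", label, "_", tail)))
      }
    }
    NULL
  })

  ## -- manifest
  manifest <- file.path(config$out_dir, "manifest.txt")
  md5 <- function(f) if (!is.null(f)) unname(tools::md5sum(f)) else NULL
  lines <- c(
    paste0("package_version = ", as.character(utils::packageVersion("cpmconn"))),
    paste0("r_version = ", R.version.string),
    paste0("seed = ", config$seed),
    paste0("simulate = ", config$simulate),
    if (!config$simulate) paste0("edges_md5 = ", md5(config$edges_file)),
    if (!config$simulate) paste0("pheno_md5 = ", md5(config$pheno_file)),
    paste0("p_threshold = ", config$p_threshold),
    paste0("n_perm = ", config$n_perm),
    paste0("harmonize = ", config$harmonize, " (", config$combat_mode, ")"),
    paste0("scores = ", paste(config$scores, collapse = ",")),
    paste0("subtypes = ", paste(config$subtypes, collapse = ",")),
    paste0("models_fit = ", paste(names(models), collapse = ",")),
    paste0("timings_s = ", paste(names(timings), unlist(timings),
                                 sep = ":", collapse = ",")))
  writeLines(lines, manifest)
  logln("pipeline complete")

  invisible(list(models = models, validation = validation,
                 cpm_summary = cpm_summary,
                 validation_summary = validation_summary,
                 pheno = pheno, edges = edges, atlas = dat$atlas,
                 truth = dat$truth, out_dir = config$out_dir,
                 config = config))
}
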