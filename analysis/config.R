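# Shared configuration for the analysis scripts (01..06).
#
# Every script regenerates what it needs from this seed — generation is
# deterministic and takes well under a second, so no intermediate bulk
# data files are passed between scripts; only the small result tables
# under results/ are written.

library(cpmconn)

SEED <- 20231127
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# Study-replica conditions: 151-patient model sample, 172-patient
# validation sample, 36 controls; 160-node six-network connectome; 40
# planted negative edges at 1.5 z-units per behaviour SD against unit
# edge noise; additive + multiplicative per-site effects.
STUDY_SPEC <- generator_spec()

N_PERM <- 200
P_THRESHOLD <- 0.01
SCORES <- c("total", "communication")
CPM_COVARIATES <- c("age", "sex", "mfd")

make_dataset <- function() generate(STUDY_SPEC, SEED)

covariate_matrix <- function(pheno) {
  cbind(age = pheno$age, sexM = as.numeric(pheno$sex == "M"),
        mfd = pheno$mfd)
}

# Filtered, per-sample harmonized analysis set, as used by every
# downstream script.
prepare_analysis_set <- function(ds = make_dataset()) {
  keep <- unlist(lapply(unique(ds$pheno$sample), function(sm) {
    # site-size rule applies to the patient cohorts, not the small
    # control sample
    fc <- filter_config(min_site_size = if (sm == "control") NULL else 20)
    filter_subjects(ds$pheno[ds$pheno$sample == sm, ], fc)$included
  }))
  pheno <- ds$pheno[ds$pheno$subject_id %in% keep, ]
  edges <- ds$edges[pheno$subject_id, ]
  for (sm in unique(pheno$sample)) {
    rows <- pheno$sample == sm
    covs <- pheno[rows, c("age", "sex", "fiq", "mfd")]
    edges[rows, ] <- combat_fit_transform(
      edges[rows, ], pheno$site[rows], covariates = covs,
      allow_singleton_sites = TRUE)$features
  }
  list(edges = edges, pheno = pheno, atlas = ds$atlas, truth = ds$truth)
}
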