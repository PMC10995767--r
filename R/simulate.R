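# Deterministic child seeds: one global seed expands into per-stage
# streams keyed by a label, so adding a stage never perturbs another
# stage's draws.
.child_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((seed %% 2147483647 + h * 48271) %% 2147483647)
}

#' Simulation configuration
#'
#' Parameters controlling every synthetic modality. Defaults encode the
#' planted-effect conditions the downstream recovery tests are run under:
#' a protective patient-level bias effect of ln(OR) = -1 on mortality, a
#' bulk survival hazard ratio of 3 between the bottom and top pentile of
#' the bias score, a four-fold ligand-receptor co-expression effect inside
#' the planted spatial region, and CMV reference-chain detection rates of
#' 0.3 in seropositive versus 0.01 in seronegative subjects at a
#' repertoire depth of 10,000 unique chains.
#'
#' @param seed integer seed; together with the config it fully determines
#'   all outputs.
#' @param n_patients cohort size.
#' @param cells_per_patient_per_type cells simulated per patient for each
#'   of NK and CD8T.
#' @param true_lnOR_bias,true_lnOR_sex,true_lnOR_age planted log odds
#'   ratios on mortality (age per standard deviation).
#' @param baseline_logit intercept of the outcome model.
#' @param bias_prevalence fraction of patients with the latent NKG2A+ bias.
#' @param a_fraction_biased,a_fraction_unbiased fraction of NKG2A+ cells
#'   among A/C-committed cells for biased versus unbiased patients.
#' @param assigned_fraction fraction of cells committed to either marker
#'   population (the rest remain marker-negative).
#' @param noise_sd standard deviation of the log-normal perturbation on
#'   the ln(CPM+1) scale.
#' @param n_bulk bulk cohort size.
#' @param bulk_hazard_ratio hazard of bottom-pentile over top-pentile
#'   samples.
#' @param base_hazard daily baseline hazard of top-pentile samples.
#' @param censor_hazard daily hazard of independent exponential censoring
#'   (0 disables censoring).
#' @param grid_dims hex grid dimensions (rows, cols) in spots.
#' @param region_size spots in each planted CD8 T cell region.
#' @param n_lr_pairs total ligand-receptor pairs simulated.
#' @param n_planted_pairs pairs receiving the co-expression effect.
#' @param lr_effect multiplicative ligand/receptor expression factor inside
#'   the planted NKG2A+ region.
#' @param n_subjects repertoire subjects.
#' @param cmv_prevalence fraction of CMV-positive subjects.
#' @param repertoire_depth unique chains per repertoire.
#' @param cmv_match_rate_pos,cmv_match_rate_neg per-reference-clone
#'   detection probability by serostatus.
#' @param reference_list_size synthetic CMV reference list size (164,
#'   mirroring the published chain list).
#' @param n_marker_cells,n_background_genes,marker_effect marker-population
#'   simulation: cells, background genes, and the ln(CPM+1) elevation of
#'   population markers over baseline.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 200,
                       cells_per_patient_per_type = 25,
                       true_lnOR_bias = -1.0,
                       true_lnOR_sex = -0.2,
                       true_lnOR_age = 0.4,
                       baseline_logit = -1.0,
                       bias_prevalence = 0.4,
                       a_fraction_biased = 0.9,
                       a_fraction_unbiased = 0.1,
                       assigned_fraction = 0.6,
                       noise_sd = 0.5,
                       n_bulk = 500,
                       bulk_hazard_ratio = 3,
                       base_hazard = 1 / 1000,
                       censor_hazard = 1 / 3000,
                       grid_dims = c(20, 20),
                       region_size = 30,
                       n_lr_pairs = 40,
                       n_planted_pairs = 3,
                       lr_effect = 4,
                       n_subjects = 100,
                       cmv_prevalence = 0.5,
                       repertoire_depth = 10000,
                       cmv_match_rate_pos = 0.3,
                       cmv_match_rate_neg = 0.01,
                       reference_list_size = 164,
                       n_marker_cells = 2000,
                       n_background_genes = 50,
                       marker_effect = 2.0) {
  cfg <- as.list(environment())
  fracs <- c(cfg$bias_prevalence, cfg$a_fraction_biased,
             cfg$a_fraction_unbiased, cfg$assigned_fraction,
             cfg$cmv_prevalence, cfg$cmv_match_rate_pos,
             cfg$cmv_match_rate_neg)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$a_fraction_biased <= cfg$a_fraction_unbiased)
    warning("a_fraction_biased <= a_fraction_unbiased: ",
            "planted effect direction is inverted")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a single-cell cohort with planted patient bias
#'
#' Per patient: a latent NKG2A+ bias flag (Bernoulli at the configured
#' prevalence), NK and CD8 T cells whose KLRD1/KLRC1/KLRC2 ln(CPM+1)
#' expression is drawn so the threshold rule recovers each cell's planted
#' marker label with small known error, and a mortality outcome drawn from
#' `Bernoulli(logistic(baseline + lnOR_bias*bias + lnOR_sex*female +
#' lnOR_age*age_std))`. Ground truth (latent flags, per-cell labels) is
#' emitted alongside and never consumed by the analysis stages.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (`ExpressionMatrix`, ln_cpm1), `cells`
#'   (data.frame `cell_id`, `patient_id`, `cell_type`, `timepoint`,
#'   `phase`), `patients` (data.frame with demographics and `deceased`),
#'   and `truth` (`latent_bias` per patient, `cell_label` per cell).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(.child_seed(config$seed, "cohort"))
  np <- config$n_patients
  cpp <- config$cells_per_patient_per_type
  patient_id <- sprintf("P%04d", seq_len(np))
  latent <- stats::rbinom(np, 1, config$bias_prevalence)
  sex_female <- stats::rbinom(np, 1, 0.5)
  age <- pmax(18, stats::rnorm(np, 60, 15))
  age_std <- (age - mean(age)) / stats::sd(age)
  eta <- config$baseline_logit + config$true_lnOR_bias * latent +
    config$true_lnOR_sex * sex_female + config$true_lnOR_age * age_std
  deceased <- stats::rbinom(np, 1, stats::plogis(eta))
  severity_wos <- sample(0:8, np, replace = TRUE)

  n_cells <- np * 2L * cpp
  pat_idx <- rep(seq_len(np), each = 2L * cpp)
  cell_type <- rep(rep(c("NK", "CD8T"), each = cpp), np)
  a_frac <- ifelse(latent[pat_idx] == 1, config$a_fraction_biased,
                   config$a_fraction_unbiased)
  committed <- stats::rbinom(n_cells, 1, config$assigned_fraction) == 1
  is_a <- stats::rbinom(n_cells, 1, a_frac) == 1
  label <- ifelse(!committed, "UNASSIGNED",
                  ifelse(is_a, "NKG2A_POS", "NKG2C_POS"))

  sd_ <- config$noise_sd
  hi <- function(n) pmax(0, stats::rnorm(n, 3.5, sd_))
  lo <- function(n) pmax(0, stats::rnorm(n, 0.8, sd_))
  klrd1 <- ifelse(committed, hi(n_cells), lo(n_cells))
  klrc1 <- ifelse(committed & is_a, hi(n_cells), lo(n_cells))
  klrc2 <- ifelse(committed & !is_a, hi(n_cells), lo(n_cells))
  vals <- rbind(KLRD1 = klrd1, KLRC1 = klrc1, KLRC2 = klrc2)
  cell_id <- sprintf("C%06d", seq_len(n_cells))
  colnames(vals) <- cell_id

  list(expr = expression_matrix(vals, "ln_cpm1"),
       cells = data.frame(cell_id = cell_id,
                          patient_id = patient_id[pat_idx],
                          cell_type = cell_type,
                          timepoint = "T1", phase = "acute",
                          stringsAsFactors = FALSE),
       patients = data.frame(patient_id = patient_id,
                             sex_female = sex_female,
                             age_years = age, age_std = age_std,
                             severity_wos = severity_wos,
                             deceased = deceased,
                             stringsAsFactors = FALSE),
       truth = list(latent_bias = stats::setNames(latent, patient_id),
                    cell_label = stats::setNames(label, cell_id)))
}

#' Simulate bulk samples with pentile-dependent survival
#'
#' KLRD1/KLRC1/KLRC2 expression is drawn log-normally around a latent
#' per-sample bias axis so the pentiles of the CD94-product score are well
#' defined. Survival is exponential: top-pentile (NKG2A-high) samples get
#' the baseline hazard, bottom-pentile samples the baseline times the
#' configured hazard ratio, middle samples the geometric mean of the two.
#' Censoring is independent exponential.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (`ExpressionMatrix`, bulk_norm), `samples`
#'   (data.frame `sample_id`, `score`, `pentile`, `time`, `event`), and
#'   `truth` (`latent_axis`, `hazard` per sample).
#' @export
simulate_bulk <- function(config = sim_config()) {
  n <- config$n_bulk
  if (n < 10) stop("bulk simulation needs at least 10 samples")
  set.seed(.child_seed(config$seed, "bulk"))
  axis <- stats::rnorm(n)
  sd_ <- config$noise_sd
  klrd1 <- exp(stats::rnorm(n, 1, sd_))
  klrc1 <- exp(0.8 * axis + stats::rnorm(n, 0, sd_))
  klrc2 <- exp(-0.8 * axis + stats::rnorm(n, 0, sd_))
  vals <- rbind(KLRD1 = klrd1, KLRC1 = klrc1, KLRC2 = klrc2)
  sample_id <- sprintf("S%04d", seq_len(n))
  colnames(vals) <- sample_id
  expr <- expression_matrix(vals, "bulk_norm")
  score <- score_bulk(expr)
  pent <- call_bulk_pentiles(score)
  h0 <- config$base_hazard
  hazard <- rep(h0 * sqrt(config$bulk_hazard_ratio), n)
  hazard[pent == "NKG2A_POS"] <- h0
  hazard[pent == "NKG2C_POS"] <- h0 * config$bulk_hazard_ratio
  t_event <- stats::rexp(n, hazard)
  if (config$censor_hazard > 0) {
    t_cens <- stats::rexp(n, config$censor_hazard)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  list(expr = expr,
       samples = data.frame(sample_id = sample_id, score = score,
                            pentile = as.character(pent),
                            time = time, event = event,
                            stringsAsFactors = FALSE),
       truth = list(latent_axis = stats::setNames(axis, sample_id),
                    hazard = stats::setNames(hazard, sample_id)))
}

# Grow a contiguous region of `k` spots by breadth-first expansion from a
# random seed spot, excluding `exclude` indices.
.grow_region <- function(grid, k, exclude = integer(0), max_tries = 20) {
  n <- nrow(grid$spots)
  avail <- setdiff(seq_len(n), exclude)
  for (try in seq_len(max_tries)) {
    start <- if (length(avail) == 1) avail else sample(avail, 1)
    region <- start
    frontier <- start
    while (length(region) < k && length(frontier)) {
      nb <- setdiff(unique(unlist(grid$adjacency[frontier])),
                    c(region, exclude))
      if (!length(nb)) break
      take <- utils::head(nb, k - length(region))
      region <- c(region, take)
      frontier <- take
    }
    if (length(region) == k) return(region)
  }
  stop("could not grow a contiguous region of ", k, " spots")
}

#' Simulate spatial data with a planted NKG2A+ CD8 T cell region
#'
#' Builds a hex grid, plants one contiguous region of NKG2A+ CD8 T cell
#' spots (CD3D/E/G, CD8A/B and KLRC1 expressed) and a disjoint region of
#' NKG2A- CD8 T cell spots (same T/CD8 markers, KLRC1 = 0), and simulates
#' a ligand-receptor panel whose planted pairs have ligand and receptor
#' expression multiplied by `lr_effect` inside the NKG2A+ region.
#'
#' @param config a [sim_config()].
#' @param noiseless if TRUE, marker expression is set to fixed positive
#'   values with no noise (planted classes recoverable exactly).
#' @return list with `grid`, `expr` (`ExpressionMatrix`, spatial_counts),
#'   `pairs` (an `LRPairs` table), and `truth` (`pos_spots`, `neg_spots`,
#'   `planted_pairs`).
#' @export
simulate_spatial <- function(config = sim_config(), noiseless = FALSE) {
  set.seed(.child_seed(config$seed, "spatial"))
  grid <- make_grid(config$grid_dims[1], config$grid_dims[2], "hex")
  n <- nrow(grid$spots)
  k <- config$region_size
  pos_idx <- .grow_region(grid, k)
  neg_idx <- .grow_region(grid, k,
                          exclude = c(pos_idx,
                                      unlist(grid$adjacency[pos_idx])))
  ids <- grid$spots$spot_id

  markers <- c("CD3D", "CD3E", "CD3G", "CD8A", "CD8B", "KLRC1")
  lig_genes <- sprintf("LIG%02d", seq_len(config$n_lr_pairs))
  rec_genes <- sprintf("REC%02d", seq_len(config$n_lr_pairs))
  vals <- matrix(0, length(markers) + 2 * config$n_lr_pairs, n,
                 dimnames = list(c(markers, lig_genes, rec_genes), ids))
  cd8_idx <- c(pos_idx, neg_idx)
  draw <- function(m) if (noiseless) rep(1, m) else
    exp(stats::rnorm(m, 0, config$noise_sd))
  for (g in c("CD3D", "CD3E", "CD3G", "CD8A", "CD8B"))
    vals[g, cd8_idx] <- draw(length(cd8_idx))
  vals["KLRC1", pos_idx] <- draw(length(pos_idx))

  planted <- sort(sample(config$n_lr_pairs, config$n_planted_pairs))
  for (p in seq_len(config$n_lr_pairs)) {
    boost <- if (p %in% planted) config$lr_effect else 1
    vals[lig_genes[p], cd8_idx] <- draw(length(cd8_idx))
    vals[rec_genes[p], cd8_idx] <- draw(length(cd8_idx))
    vals[lig_genes[p], pos_idx] <- vals[lig_genes[p], pos_idx] * boost
    vals[rec_genes[p], pos_idx] <- vals[rec_genes[p], pos_idx] * boost
  }
  pairs <- lr_pairs(sprintf("pair%02d", seq_len(config$n_lr_pairs)),
                    lig_genes, rec_genes)
  list(grid = grid,
       expr = expression_matrix(vals, "spatial_counts"),
       pairs = pairs,
       truth = list(pos_spots = ids[pos_idx], neg_spots = ids[neg_idx],
                    planted_pairs = pairs$pair_id[planted]))
}

#' Simulate TCR-beta repertoires with planted CMV enrichment
#'
#' A synthetic reference list of unique chains stands in for the published
#' CMV-associated list. Each subject's repertoire holds
#' `repertoire_depth` unique chains; every reference clone is included
#' independently with probability `cmv_match_rate_pos` for seropositive
#' subjects and `cmv_match_rate_neg` for seronegative ones, the remainder
#' filled with random non-reference chains.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (chain data.frame), `repertoires` (list
#'   of `Repertoire`), and `truth` (`cmv_status` per subject).
#' @export
simulate_repertoires <- function(config = sim_config()) {
  set.seed(.child_seed(config$seed, "repertoire"))
  ref <- .random_chains(config$reference_list_size)
  ref_key <- .chain_key(ref)
  ns <- config$n_subjects
  status <- stats::rbinom(ns, 1, config$cmv_prevalence)
  subj <- sprintf("R%03d", seq_len(ns))
  # sequencing depth varies between subjects around the nominal value
  depth <- pmax(100, round(config$repertoire_depth *
                             exp(stats::rnorm(ns, 0, 0.1))))
  reps <- vector("list", ns)
  for (i in seq_len(ns)) {
    rate <- if (status[i] == 1) config$cmv_match_rate_pos else
      config$cmv_match_rate_neg
    take <- stats::runif(nrow(ref)) < rate
    fill_n <- depth[i] - sum(take)
    fill <- .random_chains(max(0, fill_n))
    fill <- fill[!(.chain_key(fill) %in% ref_key), , drop = FALSE]
    reps[[i]] <- repertoire(subj[i], subj[i],
                            rbind(ref[take, , drop = FALSE], fill))
  }
  list(reference = ref, repertoires = reps,
       truth = list(cmv_status = stats::setNames(status, subj)))
}

#' Simulate marker-defined CD8 T cell populations
#'
#' Five planted populations, each elevating its literature markers on the
#' ln(CPM+1) scale: proliferation (MKI67), MAIT (KLRB1), memory (IL7R),
#' SLEC-like (B3GAT1 and IFNG, plus GZMB to exercise rule precedence),
#' and effector (GZMB). Background genes carry noise only.
#'
#' @param config a [sim_config()].
#' @param noiseless if TRUE marker elevations are exact with zero noise.
#' @return list with `expr` (`ExpressionMatrix`, ln_cpm1) and `truth`
#'   (`population` per cell).
#' @export
simulate_marker_populations <- function(config = sim_config(),
                                        noiseless = FALSE) {
  set.seed(.child_seed(config$seed, "markers"))
  pops <- c("proliferation", "MAIT", "memory", "SLEC-like", "effector")
  up <- list(proliferation = "MKI67", MAIT = "KLRB1", memory = "IL7R",
             `SLEC-like` = c("B3GAT1", "IFNG", "GZMB"),
             effector = "GZMB")
  n <- config$n_marker_cells
  markers <- c("MKI67", "KLRB1", "IL7R", "B3GAT1", "IFNG", "GZMB")
  bg <- sprintf("BG%03d", seq_len(config$n_background_genes))
  pop <- sample(pops, n, replace = TRUE)
  sd_ <- if (noiseless) 0 else config$noise_sd
  # heterogeneous per-gene baselines, as in real transcriptomes; markers
  # share the same baseline so only the planted elevation separates them
  base <- c(rep(1.0, length(markers)),
            stats::runif(length(bg), 0.5, 2.5))
  vals <- matrix(stats::rnorm((length(markers) + length(bg)) * n, base, sd_),
                 length(markers) + length(bg), n,
                 dimnames = list(c(markers, bg), sprintf("M%05d", seq_len(n))))
  for (p in pops) {
    j <- pop == p
    vals[up[[p]], j] <- vals[up[[p]], j] + config$marker_effect
  }
  vals <- pmax(vals, 0)
  list(expr = expression_matrix(vals, "ln_cpm1"),
       truth = list(population = stats::setNames(pop, colnames(vals))))
}
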