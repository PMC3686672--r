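#' Scenario for simulating an eight-organ expression atlas
#'
#' Describes a negative-binomial count simulation emulating a single-library
#' transcriptome atlas across eight organs (mantle, female gonad, adductor
#' muscle, hemolymph, digestive gland, gill, labial palps, male gonad), with
#' a configurable fraction of shell-matrix-protein (SMP) genes and, among
#' them, of genes whose expression is suppressed in the mantle (and
#' optionally the hemolymph) but elevated elsewhere — the ground truth for
#' testing the origin classifier.
#'
#' Per-gene relative abundances are log-normal; per-(gene, organ) biological
#' variation is a mild log-normal multiplier; counts are a single NB draw
#' per gene per library (one pooled library per organ, no replicates).
#' Injected non-mantle genes get their organ means set in RPKM space:
#' suppressed organs at `suppressed_rpkm`, one randomly chosen supporting
#' organ at `elevated_rpkm`.
#'
#' @param n_genes number of genes.
#' @param organ_labels ordered organ labels; the first is taken as the
#'   mantle and `hemolymph_label` must be among them.
#' @param library_sizes per-organ sequencing depth (recycled; jittered
#'   multiplicatively by `depth_jitter_sdlog`).
#' @param gene_length_range bp interval for uniform gene lengths.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene relative abundance.
#' @param organ_sdlog log-sd of the per-(gene, organ) biological multiplier.
#' @param dispersion NB size parameter (variance = mu + mu^2/size);
#'   `Inf` (the default) is the Poisson limit: sampling noise only, the
#'   regime in which an exact two-library test of one pooled library per
#'   condition is calibrated.  Finite values add between-pool biological
#'   overdispersion.
#' @param frac_shell_protein fraction of genes flagged as SMP genes.
#' @param frac_nonmantle_origin fraction of SMP genes injected as
#'   non-mantle-origin.
#' @param frac_nonmantle_nonhemolymph fraction of the injected non-mantle
#'   genes that are also hemolymph-suppressed.
#' @param mantle_boost multiplicative mantle boost applied to non-injected
#'   SMP genes (the atlas signature that the mantle is the main producer).
#' @param suppressed_rpkm,elevated_rpkm expected RPKM targets for the
#'   suppressed and supporting organs of injected genes.
#' @param depth_jitter_sdlog log-sd of the library-size jitter.
#' @param seed integer seed; every simulation from the same scenario is
#'   bit-identical.
#' @return A list of class `atlas_scenario`.
#' @export
atlas_scenario <- function(n_genes = 10000,
                           organ_labels = c("Man", "Fgo", "Amu", "Hem",
                                            "Dgl", "Gil", "Lpa", "Mgo"),
                           library_sizes = 1e7,
                           gene_length_range = c(300, 10000),
                           baseline_log_mean = 0,
                           baseline_log_sd = 1.2,
                           organ_sdlog = 0.15,
                           dispersion = Inf,
                           frac_shell_protein = 0.1,
                           frac_nonmantle_origin = 0.01,
                           frac_nonmantle_nonhemolymph = 0.5,
                           mantle_boost = 3,
                           suppressed_rpkm = 1,
                           elevated_rpkm = 20,
                           depth_jitter_sdlog = 0.1,
                           seed = 1) {
  sc <- list(n_genes = n_genes, organ_labels = organ_labels,
             library_sizes = rep_len(library_sizes, length(organ_labels)),
             gene_length_range = gene_length_range,
             baseline_log_mean = baseline_log_mean,
             baseline_log_sd = baseline_log_sd,
             organ_sdlog = organ_sdlog, dispersion = dispersion,
             frac_shell_protein = frac_shell_protein,
             frac_nonmantle_origin = frac_nonmantle_origin,
             frac_nonmantle_nonhemolymph = frac_nonmantle_nonhemolymph,
             mantle_boost = mantle_boost,
             suppressed_rpkm = suppressed_rpkm,
             elevated_rpkm = elevated_rpkm,
             depth_jitter_sdlog = depth_jitter_sdlog,
             seed = seed)
  validate_atlas_scenario(sc)
  structure(sc, class = "atlas_scenario")
}

validate_atlas_scenario <- function(sc) {
  if (!is.numeric(sc$n_genes) || sc$n_genes < 1)
    stop("invalid scenario: n_genes must be a positive integer")
  if (anyDuplicated(sc$organ_labels))
    stop("invalid scenario: organ_labels must be unique")
  if (length(sc$organ_labels) < 2)
    stop("invalid scenario: organ_labels needs at least mantle plus one organ")
  if (any(sc$library_sizes <= 0))
    stop("invalid scenario: library_sizes must be positive")
  for (f in c("frac_shell_protein", "frac_nonmantle_origin",
              "frac_nonmantle_nonhemolymph"))
    if (sc[[f]] < 0 || sc[[f]] > 1)
      stop("invalid scenario: ", f, " must lie in [0, 1]")
  if (length(sc$gene_length_range) != 2 || sc$gene_length_range[1] <= 0 ||
      diff(sc$gene_length_range) < 0)
    stop("invalid scenario: gene_length_range must be a positive interval")
  if (sc$dispersion <= 0) stop("invalid scenario: dispersion must be positive")
  invisible(sc)
}

# single NB draw per cell; dispersion = Inf is the Poisson limit
# (sequencing sampling noise only, the regime in which an exact two-library
# test is calibrated)
rnbinom_matrix <- function(mu, size) {
  draws <- if (is.infinite(size)) stats::rpois(length(mu), as.vector(mu))
           else stats::rnbinom(length(mu), mu = as.vector(mu), size = size)
  m <- matrix(draws, nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(m) <- "double"
  m
}

#' Simulate an organ-atlas count matrix with known ground truth
#'
#' @param scenario an [atlas_scenario()].
#' @return A list with elements `counts` (a [count_matrix()], one column per
#'   organ) and `truth` (data.frame: `gene_id`, `is_smp`, `origin_class`,
#'   `injected` — `origin_class` is derived by applying the classification
#'   rules to the noiseless expected RPKM, so labels partition the SMP
#'   genes; `injected` marks the genes whose suppression was planted).
#' @export
simulate_organ_atlas <- function(scenario) {
  validate_atlas_scenario(scenario)
  sc <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sc$seed)

  G <- sc$n_genes
  organs <- sc$organ_labels
  mantle <- organs[1]
  hemo <- if ("Hem" %in% organs) "Hem" else organs[min(4, length(organs))]
  ids <- sprintf("gene%05d", seq_len(G))
  lens <- round(stats::runif(G, sc$gene_length_range[1], sc$gene_length_range[2]))
  depths <- round(sc$library_sizes *
                    stats::rlnorm(length(organs), 0, sc$depth_jitter_sdlog))
  names(depths) <- organs

  # per-gene relative abundance, normalized so expected column sums track depth
  u <- stats::rlnorm(G, sc$baseline_log_mean, sc$baseline_log_sd)
  rel <- u / sum(u)

  n_smp <- floor(sc$frac_shell_protein * G)
  smp_idx <- seq_len(n_smp)                     # leading block; ids are arbitrary
  n_inj <- floor(sc$frac_nonmantle_origin * n_smp)
  inj_idx <- smp_idx[seq_len(n_inj)]
  n_inj_nh <- floor(sc$frac_nonmantle_nonhemolymph * n_inj)
  inj_nh_idx <- inj_idx[seq_len(n_inj_nh)]

  # expected mean matrix: baseline x organ-level biological noise
  mult <- matrix(stats::rlnorm(G * length(organs), 0, sc$organ_sdlog),
                 G, length(organs), dimnames = list(ids, organs))
  mu <- outer(rel, rep(1, length(organs))) * mult
  dimnames(mu) <- list(ids, organs)
  mu <- sweep(mu, 2, depths, `*`)

  # mantle boost for non-injected SMP genes
  boost_idx <- setdiff(smp_idx, inj_idx)
  mu[boost_idx, mantle] <- mu[boost_idx, mantle] * sc$mantle_boost

  # injected non-mantle genes: means pinned in RPKM space
  if (n_inj) {
    rpkm_to_mu <- function(rpkm, idx, organ)
      rpkm * lens[idx] * depths[organ] / 1e9
    support_pool <- setdiff(organs, c(mantle, hemo))
    support <- sample(support_pool, n_inj, replace = TRUE)
    for (j in seq_len(n_inj)) {
      i <- inj_idx[j]
      for (o in setdiff(organs, mantle))
        mu[i, o] <- rpkm_to_mu(sc$suppressed_rpkm, i, o)
      mu[i, mantle] <- rpkm_to_mu(sc$suppressed_rpkm, i, mantle)
      mu[i, support[j]] <- rpkm_to_mu(sc$elevated_rpkm, i, support[j])
      if (!(i %in% inj_nh_idx))  # hemolymph stays expressed for the 27-only class
        mu[i, hemo] <- rpkm_to_mu(sc$elevated_rpkm / 2, i, hemo)
    }
  }

  # renormalize each library to its target depth: boosting or suppressing a
  # subset of genes changes the composition, not the sequencing depth
  mu <- sweep(mu, 2, depths / colSums(mu), `*`)

  counts <- rnbinom_matrix(mu, sc$dispersion)
  cm <- count_matrix(counts, gene_lengths = lens, library_sizes = depths)

  # truth labels from the noiseless expected RPKM, using the same rules the
  # classifier applies (threshold 5, twofold vs mantle)
  erpkm <- 1e9 * sweep(sweep(mu, 1, lens, `/`), 2, depths, `/`)
  tmin <- 5; fold <- 2
  em <- erpkm[, mantle]
  eh <- erpkm[, hemo]
  eo <- erpkm[, setdiff(organs, mantle), drop = FALSE]
  has_other <- rowSums(eo > tmin & eo >= fold * em) > 0
  nm <- em < tmin & has_other
  cls <- ifelse(nm & eh < tmin, "non_mantle_non_hemolymph",
         ifelse(nm, "non_mantle",
         ifelse(em > tmin, "mantle_expressed", "unexpressed_everywhere")))

  truth <- data.frame(gene_id = ids,
                      is_smp = seq_len(G) %in% smp_idx,
                      origin_class = cls,
                      injected = seq_len(G) %in% inj_idx,
                      stringsAsFactors = FALSE)
  list(counts = cm, truth = truth, scenario = sc)
}

#' Scenario for simulating a shell-damage time course
#'
#' Emulates the damage experiment: for each of seven post-damage dates one
#' pooled library per mantle side (left = damaged, right = undamaged) plus
#' one control library per side.  A configurable fraction of genes is
#' damage-responsive: their left-side treated means carry `effect_fold` on
#' `persistence` randomly chosen dates.  Transient genes carry the effect on
#' only 1-2 random dates.  The right side is a pure null.
#'
#' @param n_genes number of genes.
#' @param dates strictly increasing day labels.
#' @param sides side labels; the first is the damaged side.
#' @param library_sizes target depth per library (recycled over all
#'   columns; jittered by `depth_jitter_sdlog`).
#' @param baseline_log_mean,baseline_log_sd,dispersion,depth_jitter_sdlog
#'   as in [atlas_scenario()].
#' @param frac_damage_responsive fraction of genes with persistent left-side
#'   upregulation.
#' @param effect_fold multiplicative effect for responsive genes.
#' @param persistence number of dates (of `length(dates)`) carrying the
#'   effect for each responsive gene.
#' @param frac_transient fraction of genes with the effect on only 1-2
#'   random dates.
#' @param seed integer seed.
#' @return A list of class `timecourse_scenario`.
#' @export
timecourse_scenario <- function(n_genes = 10000,
                                dates = c(1, 3, 5, 9, 13, 17, 21),
                                sides = c("left", "right"),
                                library_sizes = 1e7,
                                baseline_log_mean = 0,
                                baseline_log_sd = 1.2,
                                dispersion = Inf,
                                frac_damage_responsive = 0.02,
                                effect_fold = 4,
                                persistence = 7,
                                frac_transient = 0.02,
                                depth_jitter_sdlog = 0.1,
                                seed = 1) {
  sc <- list(n_genes = n_genes, dates = dates, sides = sides,
             library_sizes = library_sizes,
             baseline_log_mean = baseline_log_mean,
             baseline_log_sd = baseline_log_sd,
             dispersion = dispersion,
             frac_damage_responsive = frac_damage_responsive,
             effect_fold = effect_fold, persistence = persistence,
             frac_transient = frac_transient,
             depth_jitter_sdlog = depth_jitter_sdlog, seed = seed)
  validate_timecourse_scenario(sc)
  structure(sc, class = "timecourse_scenario")
}

validate_timecourse_scenario <- function(sc) {
  if (!is.numeric(sc$n_genes) || sc$n_genes < 1)
    stop("invalid scenario: n_genes must be a positive integer")
  if (is.unsorted(sc$dates, strictly = TRUE))
    stop("invalid scenario: dates must be strictly increasing")
  if (length(sc$sides) < 1 || anyDuplicated(sc$sides))
    stop("invalid scenario: sides must be unique")
  for (f in c("frac_damage_responsive", "frac_transient"))
    if (sc[[f]] < 0 || sc[[f]] > 1)
      stop("invalid scenario: ", f, " must lie in [0, 1]")
  if (sc$persistence < 0 || sc$persistence > length(sc$dates))
    stop("invalid scenario: persistence must lie in 0..", length(sc$dates))
  if (sc$effect_fold <= 0) stop("invalid scenario: effect_fold must be positive")
  if (any(sc$library_sizes <= 0))
    stop("invalid scenario: library_sizes must be positive")
  if (sc$dispersion <= 0) stop("invalid scenario: dispersion must be positive")
  invisible(sc)
}

#' Simulate a shell-damage time-course count matrix with ground truth
#'
#' @param scenario a [timecourse_scenario()].
#' @return A list with elements `counts` (a [count_matrix()] with one column
#'   per (side, date) plus a control column per side), `manifest` (samples
#'   manifest data.frame matching the columns) and `truth` (data.frame:
#'   `gene_id`, `is_damage_responsive`, `is_transient`, `effect_dates` —
#'   comma-joined date labels carrying the effect).
#' @export
simulate_damage_timecourse <- function(scenario) {
  validate_timecourse_scenario(scenario)
  sc <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sc$seed)

  G <- sc$n_genes
  nd <- length(sc$dates)
  damaged <- sc$sides[1]
  ids <- sprintf("gene%05d", seq_len(G))
  lens <- round(stats::runif(G, 300, 10000))

  cols <- c(paste0(rep(sc$sides, each = 1), "_control"),
            paste0(rep(sc$sides, each = nd), "_d", rep(sc$dates, length(sc$sides))))
  depths <- round(rep_len(sc$library_sizes, length(cols)) *
                    stats::rlnorm(length(cols), 0, sc$depth_jitter_sdlog))
  names(depths) <- cols

  u <- stats::rlnorm(G, sc$baseline_log_mean, sc$baseline_log_sd)
  rel <- u / sum(u)

  n_resp <- floor(sc$frac_damage_responsive * G)
  n_trans <- floor(sc$frac_transient * G)
  resp_idx <- seq_len(n_resp)
  trans_idx <- n_resp + seq_len(n_trans)

  effect <- matrix(1, G, nd, dimnames = list(ids, as.character(sc$dates)))
  effect_dates <- character(G)
  if (n_resp && sc$persistence > 0) {
    for (i in resp_idx) {
      d <- sort(sample.int(nd, sc$persistence))
      effect[i, d] <- sc$effect_fold
      effect_dates[i] <- paste(sc$dates[d], collapse = ",")
    }
  }
  if (n_trans) {
    for (i in trans_idx) {
      d <- sort(sample.int(nd, sample(1:2, 1)))
      effect[i, d] <- sc$effect_fold
      effect_dates[i] <- paste(sc$dates[d], collapse = ",")
    }
  }

  mu <- matrix(0, G, length(cols), dimnames = list(ids, cols))
  for (cc in cols) {
    side <- sub("_(control|d.*)$", "", cc)
    base <- rel * depths[cc]
    if (side == damaged && grepl("_d", cc, fixed = TRUE)) {
      d <- sub(".*_d", "", cc)
      base <- base * effect[, d]
    }
    mu[, cc] <- base
  }

  counts <- rnbinom_matrix(mu, sc$dispersion)
  cm <- count_matrix(counts, gene_lengths = lens, library_sizes = depths)

  manifest <- data.frame(
    sample = cols,
    role = "timecourse",
    side = sub("_(control|d.*)$", "", cols),
    date = ifelse(grepl("_control$", cols), "control", sub(".*_d", "", cols)),
    organ = NA_character_, stringsAsFactors = FALSE)

  truth <- data.frame(gene_id = ids,
                      is_damage_responsive = seq_len(G) %in% resp_idx,
                      is_transient = seq_len(G) %in% trans_idx,
                      effect_dates = effect_dates,
                      stringsAsFactors = FALSE)
  list(counts = cm, manifest = manifest, truth = truth, scenario = sc)
}

#' Write simulation truth labels as TSV
#'
#' @param truth the `truth` data.frame from a simulation.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(truth, path) write_tsv(truth, path)

# preserve the caller's RNG state across seeded simulations
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
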