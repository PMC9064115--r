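# Seeded generator of sparse compositional case/control cohorts with
# prevalence-shift and abundance-shift biomarkers, multinomial read-sampling
# detection limits and multi-study batch structure.

#' Specify a synthetic case/control cohort
#'
#' Defines the generative model for a sparse compositional cohort: each taxon
#' has a baseline presence probability drawn from a Beta law and a log-normal
#' abundance-when-present; per sample, present taxa get latent abundances,
#' which are closed to proportions and observed through multinomial read
#' sampling at the given depth. Two disjoint biomarker regimes can be planted:
#'
#' * *prevalence-shift* taxa differ between classes in how often they are
#'   present (`prevalence_delta`, alternating case-enriched / case-depleted);
#' * *abundance-shift* taxa are fully prevalent in both classes and differ
#'   only in their log-abundance location (`abundance_lfc`, alternating sign),
#'   so presence carries no label information for them by construction.
#'
#' Defaults describe a mid-sized shotgun-style cohort: 200 cases vs 200
#' controls, 300 taxa, baseline prevalence Beta(2, 4), log-abundance locations
#' N(0, 1.5^2) with unit within-taxon scale, 20 prevalence-shift biomarkers at
#' delta 0.4, and a constant depth of 1e5 reads so the mechanical detection
#' floor sits at a relative abundance of about 1e-5 (0.001%).
#'
#' @param n_control,n_case Per-class sample counts.
#' @param n_taxa Number of taxa.
#' @param prevalence_shape Length-2 Beta shape parameters for baseline
#'   per-taxon presence probability.
#' @param location_mean,location_sd Normal law for per-taxon log-abundance
#'   location (natural log, before closure).
#' @param scale_sigma Within-taxon log-abundance standard deviation.
#' @param n_prevalence_signal,prevalence_delta Number of prevalence-shift taxa
#'   and the absolute between-class prevalence difference.
#' @param signal_location Optional fixed log-abundance location for the
#'   prevalence-shift taxa (both classes); use a low value such as `log(0.03)`
#'   to place them near the read-sampling detection limit. `NULL` draws their
#'   locations like any other taxon.
#' @param n_abundance_signal,abundance_lfc Number of abundance-shift taxa and
#'   the natural-log fold change applied in cases (alternating sign).
#' @param read_depth Per-sample read depth; constant when `depth_sdlog = 0`,
#'   else log-normal with median `read_depth`.
#' @param depth_sdlog Log-scale SD of the depth law (0 = constant depth).
#' @param n_datasets Number of datasets for [simulate_multistudy()].
#' @param batch_effect Per-dataset perturbation scale: prevalences are
#'   multiplied by `exp(N(0, batch_effect^2))` (clipped to \[0, 1\]) and
#'   log-abundance locations shifted by `N(0, batch_effect^2)`.
#' @param seed Integer seed governing all randomness.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_control = 200, n_case = 200, n_taxa = 300,
                           prevalence_shape = c(2, 4),
                           location_mean = 0, location_sd = 1.5,
                           scale_sigma = 1,
                           n_prevalence_signal = 20, prevalence_delta = 0.4,
                           signal_location = NULL,
                           n_abundance_signal = 0, abundance_lfc = log(3),
                           read_depth = 1e5, depth_sdlog = 0,
                           n_datasets = 1, batch_effect = 0, seed = 1) {
  stopifnot(
    n_control >= 1, n_case >= 1, n_taxa >= 2,
    length(prevalence_shape) == 2, all(prevalence_shape > 0),
    scale_sigma >= 0, location_sd >= 0,
    n_prevalence_signal >= 0, n_abundance_signal >= 0,
    n_prevalence_signal + n_abundance_signal <= n_taxa,
    prevalence_delta >= 0, prevalence_delta <= 1,
    read_depth >= 1, depth_sdlog >= 0,
    n_datasets >= 1, batch_effect >= 0
  )
  structure(
    list(
      n_control = as.integer(n_control), n_case = as.integer(n_case),
      n_taxa = as.integer(n_taxa), prevalence_shape = prevalence_shape,
      location_mean = location_mean, location_sd = location_sd,
      scale_sigma = scale_sigma,
      n_prevalence_signal = as.integer(n_prevalence_signal),
      prevalence_delta = prevalence_delta,
      signal_location = signal_location,
      n_abundance_signal = as.integer(n_abundance_signal),
      abundance_lfc = abundance_lfc,
      read_depth = read_depth, depth_sdlog = depth_sdlog,
      n_datasets = as.integer(n_datasets), batch_effect = batch_effect,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# MetaPhlAn-like lineage strings with a fixed nested hierarchy (3 species per
# genus, 2 genera per family, ...), so rank aggregation is exercisable on
# synthetic cohorts.
synthetic_lineages <- function(n_taxa) {
  sp <- seq_len(n_taxa)
  ge <- ceiling(sp / 3); fa <- ceiling(ge / 2); or <- ceiling(fa / 2)
  cl <- ceiling(or / 2); ph <- ceiling(cl / 3)
  sprintf(
    "k__Bacteria|p__Phylum_%02d|c__Class_%02d|o__Order_%02d|f__Family_%02d|g__Genus_%03d|s__Species_%03d",
    ph, cl, or, fa, ge, sp
  )
}

# Draw per-taxon parameters (shared across datasets of one multi-study draw).
draw_taxon_params <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n_taxa
  prev0 <- rbeta(n, spec$prevalence_shape[1], spec$prevalence_shape[2])
  loc <- rnorm(n, spec$location_mean, spec$location_sd)

  idx_prev <- seq_len(spec$n_prevalence_signal)
  idx_ab <- spec$n_prevalence_signal + seq_len(spec$n_abundance_signal)
  sign_prev <- rep_len(c(1, -1), length(idx_prev))
  sign_ab <- rep_len(c(1, -1), length(idx_ab))

  prev_control <- prev_case <- prev0
  prev_case[idx_prev] <- pmin(pmax(prev0[idx_prev] + sign_prev * spec$prevalence_delta, 0), 1)
  prev_control[idx_ab] <- prev_case[idx_ab] <- 1
  # Abundance-shift biomarkers are "present everywhere" taxa: besides forcing
  # prevalence 1, pin their location one SD above the population mean so they
  # stay clear of the read-sampling detection floor in both classes —
  # otherwise a downward fold change would turn into an observed presence
  # shift and defeat the construction.
  loc[idx_ab] <- spec$location_mean + spec$location_sd
  if (!is.null(spec$signal_location) && length(idx_prev)) {
    loc[idx_prev] <- spec$signal_location
  }
  loc_control <- loc_case <- loc
  loc_case[idx_ab] <- loc[idx_ab] + sign_ab * spec$abundance_lfc

  signal <- rep("none", n)
  signal[idx_prev] <- "prevalence"
  signal[idx_ab] <- "abundance"
  direction <- rep(NA_character_, n)
  direction[idx_prev] <- ifelse(sign_prev > 0, "case", "control")
  direction[idx_ab] <- ifelse(sign_ab > 0, "case", "control")

  lineage <- synthetic_lineages(n)
  list(
    prev_control = prev_control, prev_case = prev_case,
    loc_control = loc_control, loc_case = loc_case,
    lineage = lineage,
    truth = tibble::tibble(
      taxon = lineage, signal = signal, direction = direction,
      prev_control = prev_control, prev_case = prev_case,
      loc_control = loc_control, loc_case = loc_case
    )
  )
}

simulate_from_params <- function(params, spec, seed, study_id) {
  set.seed(seed)
  n_total <- spec$n_control + spec$n_case
  labels <- rep(c(0L, 1L), c(spec$n_control, spec$n_case))
  ids <- sprintf("%s_S%04d", study_id, seq_len(n_total))
  n <- spec$n_taxa

  counts <- matrix(0L, n_total, n, dimnames = list(ids, params$lineage))
  depths <- numeric(n_total)
  for (s in seq_len(n_total)) {
    prev <- if (labels[s] == 1L) params$prev_case else params$prev_control
    loc <- if (labels[s] == 1L) params$loc_case else params$loc_control
    z <- NULL
    for (attempt in seq_len(100L)) {
      z <- runif(n) < prev
      if (any(z)) break
    }
    if (!any(z)) {
      stop_input(sprintf("Sample %s drew zero present taxa after 100 attempts.", ids[s]))
    }
    latent <- ifelse(z, exp(loc + spec$scale_sigma * rnorm(n)), 0)
    prop <- latent / sum(latent)
    depth <- if (spec$depth_sdlog > 0) {
      max(1, round(rlnorm(1, log(spec$read_depth), spec$depth_sdlog)))
    } else {
      spec$read_depth
    }
    counts[s, ] <- rmultinom(1, size = depth, prob = prop)[, 1]
    depths[s] <- depth
  }

  rel <- counts / depths
  profile <- as_profile(
    dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(rel)),
    rank = "species", binary = FALSE
  )
  metadata <- tibble::tibble(
    sample_id = ids, study_id = study_id, label = labels, disease = "synthetic"
  )
  structure(
    list(
      profile = profile, metadata = metadata,
      counts = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                tibble::as_tibble(counts)),
      depths = setNames(depths, ids),
      truth = params$truth, spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' Simulate a synthetic case/control cohort
#'
#' Draws per-taxon parameters, then for each sample draws presence indicators
#' from the class-specific prevalences, log-normal latent abundances for the
#' present taxa, closes them to proportions, and observes multinomial read
#' counts at the sample's depth. Relative abundances are `counts / depth`, so
#' every row sums to 1 exactly and taxa with latent proportion near `1/depth`
#' drop below the detection limit mechanically.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. Identical spec and seed
#'   give bit-identical output.
#' @param study_id Study identifier written into the metadata.
#' @return A list of class `synthetic_cohort` with elements `profile`
#'   (a [profile_table()]), `metadata` (`sample_id`, `study_id`, `label`,
#'   `disease`), `counts`, `depths`, `truth` (per-taxon generating parameters
#'   and planted-signal flags) and `spec`.
#' @export
simulate_cohort <- function(spec, seed = spec$seed, study_id = "D01") {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- draw_taxon_params(spec, derive_seed(seed, "taxa"))
  simulate_from_params(params, spec, derive_seed(seed, "samples", study_id),
                       study_id)
}

#' Simulate a multi-study collection sharing one taxon universe
#'
#' Draws one set of taxon-level parameters and planted signals, then simulates
#' `spec$n_datasets` cohorts, each from a batch-perturbed copy: prevalences
#' multiplied by a log-normal factor of scale `batch_effect` (clipped to
#' \[0, 1\]) and log-abundance locations shifted by a normal of the same
#' scale. With `batch_effect = 0` the datasets are iid draws from one spec.
#'
#' @param spec A [synthetic_spec()] with `n_datasets >= 2`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of `synthetic_cohort` objects named by study id.
#' @export
simulate_multistudy <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_datasets < 2L) stop_input("`n_datasets` must be at least 2.")
  base <- draw_taxon_params(spec, derive_seed(seed, "taxa"))
  out <- lapply(seq_len(spec$n_datasets), function(d) {
    study_id <- sprintf("D%02d", d)
    params <- base
    if (spec$batch_effect > 0) {
      set.seed(derive_seed(seed, "batch", d))
      fac <- exp(rnorm(spec$n_taxa, 0, spec$batch_effect))
      shift <- rnorm(spec$n_taxa, 0, spec$batch_effect)
      params$prev_control <- pmin(params$prev_control * fac, 1)
      params$prev_case <- pmin(params$prev_case * fac, 1)
      params$loc_control <- params$loc_control + shift
      params$loc_case <- params$loc_case + shift
    }
    simulate_from_params(params, spec, derive_seed(seed, "samples", study_id),
                         study_id)
  })
  names(out) <- sprintf("D%02d", seq_len(spec$n_datasets))
  out
}

#' Rarefy a synthetic cohort's read counts to a common depth
#'
#' Subsamples `target_depth` reads without replacement from each sample's
#' count vector (multivariate hypergeometric draw) and recomputes relative
#' abundances. Rarefying can only lose taxa: detected-taxon counts never
#' increase.
#'
#' @param cohort A `synthetic_cohort`.
#' @param target_depth Target reads per sample; must not exceed any sample's
#'   current depth.
#' @param seed Integer seed.
#' @return The rarefied `synthetic_cohort`.
#' @export
rarefy_counts <- function(cohort, target_depth, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  assert_scalar_number(target_depth, "target_depth", min = 1)
  m <- as.matrix(cohort$counts[-1])
  depths <- rowSums(m)
  low <- depths < target_depth
  if (any(low)) {
    stop_input(sprintf(
      "target_depth %d exceeds the depth of sample(s): %s",
      as.integer(target_depth),
      paste(cohort$counts$sample_id[low], collapse = ", ")
    ))
  }
  set.seed(derive_seed(seed, "rarefy"))
  for (s in seq_len(nrow(m))) {
    m[s, ] <- rhyper_multi(m[s, ], target_depth)
  }
  ids <- cohort$counts$sample_id
  rel <- m / target_depth
  cohort$counts <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                    tibble::as_tibble(m))
  cohort$depths <- setNames(rep(target_depth, length(ids)), ids)
  cohort$profile <- as_profile(
    dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(rel)),
    rank = profile_rank(cohort$profile), binary = FALSE
  )
  cohort
}

# Exact multivariate hypergeometric draw via sequential univariate draws.
rhyper_multi <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- k
  tot <- sum(counts)
  for (i in seq_along(counts)) {
    if (remaining == 0L) break
    x <- rhyper(1, counts[i], tot - counts[i], remaining)
    out[i] <- x
    remaining <- remaining - x
    tot <- tot - counts[i]
  }
  out
}

#' Presence probability of a taxon under multinomial read sampling
#'
#' A taxon at latent proportion `p` observed at `depth` reads is detected
#' (count > 0) with probability `1 - (1 - p)^depth`. This is the mechanical
#' detection limit the simulator induces.
#'
#' @param p Latent proportion(s) in \[0, 1\].
#' @param depth Read depth.
#' @return Detection probability, vectorised over `p`.
#' @export
detection_probability <- function(p, depth) 1 - (1 - p)^depth
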