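#' Simulation configuration
#'
#' Assembles the parameter list controlling the synthetic cohort. Defaults
#' mirror the study conditions the package targets: 528 animals of three
#' breeds (153/193/182), eight rooms of eight breed-homogeneous pens,
#' 28 sires per breed nested in breed, daily feed consumption recorded
#' over ages 99-140 days with linear growth, AR(1) day-to-day noise and
#' sporadic multi-day intake-depression events, and an ASV table whose
#' latent composition contributes a 0.10 share of indicator variance
#' (with pen and sire shares 0.25 and 0.06).
#'
#' @param n_animals Cohort size.
#' @param breeds Named numeric vector of breed proportions.
#' @param n_rooms,pens_per_room Housing layout.
#' @param n_sires_per_breed Sires per breed (nested coding downstream).
#' @param age_start,age_end Inclusive recording window, days of age.
#' @param intake_start_mean,intake_start_sd Per-animal feed consumption at
#'   `age_start`, kg/day.
#' @param growth_slope_mean,growth_slope_sd Per-animal daily growth in
#'   consumption, kg/day per day.
#' @param noise_sd Marginal SD of the AR(1) daily noise, kg/day.
#' @param noise_phi AR(1) coefficient of the daily noise.
#' @param pen_sd SD of pen effects on daily consumption, kg/day.
#' @param miss_prob Per-day probability of a missing record.
#' @param event_prob Per-animal probability of one depression event.
#' @param event_duration Integer range (length 2) of event length, days.
#' @param event_depth_mean,event_depth_sd Depression depth, kg/day.
#' @param visits_max Maximum feeder visits per day.
#' @param n_asv Number of ASVs simulated.
#' @param base_log_sd SD of the ASV base log-abundances.
#' @param n_factors,factor_sd Rank and loading SD of the latent community
#'   factors generating between-animal co-occurrence structure; each
#'   animal draws standard-normal factor scores and each ASV loads on the
#'   factors with N(0, `factor_sd`) weights.
#' @param animal_log_sd SD of idiosyncratic per-animal, per-ASV
#'   log-abundance noise on top of the factor structure.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters.
#' @param low_depth_frac Fraction of samples planted below depth 700.
#' @param n_informative ASVs carrying the microbial effect.
#' @param m2 Target microbial share of indicator variance.
#' @param pen_share,sire_share Target pen and sire shares.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 528,
                       breeds = c(DR = 153, LR = 193, LW = 182) / 528,
                       n_rooms = 8, pens_per_room = 8,
                       n_sires_per_breed = 28,
                       age_start = 99, age_end = 140,
                       intake_start_mean = 2.0, intake_start_sd = 0.3,
                       growth_slope_mean = 0.02, growth_slope_sd = 0.005,
                       noise_sd = 0.15, noise_phi = 0.3,
                       pen_sd = 0.1, miss_prob = 0.02,
                       event_prob = 0.3, event_duration = c(3, 7),
                       event_depth_mean = 1.0, event_depth_sd = 0.3,
                       visits_max = 8,
                       n_asv = 1000, base_log_sd = 1.0,
                       n_factors = 25, factor_sd = 0.35,
                       animal_log_sd = 0.4,
                       depth_meanlog = log(50000), depth_sdlog = 0.6,
                       low_depth_frac = 0.05,
                       n_informative = 50, m2 = 0.10,
                       pen_share = 0.25, sire_share = 0.06) {
  stopifnot(m2 >= 0, pen_share >= 0, sire_share >= 0)
  if (m2 + pen_share + sire_share >= 1) {
    abort("variance shares must sum to less than 1")
  }
  stopifnot(abs(sum(breeds) - 1) < 1e-8, event_prob >= 0, event_prob <= 1,
            miss_prob >= 0, miss_prob <= 1, low_depth_frac >= 0,
            low_depth_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate cohort metadata
#'
#' Assigns animals to breeds, breed-homogeneous pens inside rooms, and
#' sires nested within breed. Offspring of each sire are interleaved
#' across their breed's pens so paternal half-sibs are spread over pens
#' (and hence rooms), keeping sire and pen effects unconfounded.
#'
#' @param config A [sim_config()] list.
#' @param seed Seed for the assignment.
#' @return Tibble `animal_id, breed, room_id, pen_id, sire_id`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_animals
  breeds <- names(config$breeds)
  n_breed <- floor(config$breeds * n)
  rem <- n - sum(n_breed)
  if (rem > 0) {
    extra <- order(config$breeds * n - n_breed, decreasing = TRUE)[seq_len(rem)]
    n_breed[extra] <- n_breed[extra] + 1
  }
  n_pens <- config$n_rooms * config$pens_per_room
  pens_breed <- floor(n_breed / n * n_pens)
  pens_breed[pens_breed == 0] <- 1
  while (sum(pens_breed) < n_pens) {
    i <- which.max(n_breed / pens_breed)
    pens_breed[i] <- pens_breed[i] + 1
  }
  while (sum(pens_breed) > n_pens) {
    i <- which.max(pens_breed)
    pens_breed[i] <- pens_breed[i] - 1
    if (any(pens_breed == 0)) abort("infeasible pen layout for breed counts")
  }
  pen_ids <- sprintf("pen%02d", seq_len(n_pens))
  room_of_pen <- rep(sprintf("room%d", seq_len(config$n_rooms)),
                     each = config$pens_per_room)
  pen_breed <- rep(breeds, pens_breed)

  rows <- purrr::list_rbind(purrr::map(seq_along(breeds), function(bi) {
    b <- breeds[bi]
    nb <- n_breed[bi]
    sires <- sprintf("%s_s%02d", b, seq_len(config$n_sires_per_breed))
    sire_assign <- rep(sires, length.out = nb)
    # interleave offspring: order by within-sire index so consecutive
    # animals come from different sires, then deal into the breed's pens
    ord <- order(stats::ave(seq_len(nb), sire_assign, FUN = seq_along),
                 sample.int(nb))
    my_pens <- pen_ids[pen_breed == b]
    if (length(my_pens) == 0) abort("breed without pens")
    max_off <- max(table(sire_assign))
    if (max_off > length(my_pens) * 2) {
      abort("more offspring per sire than the pen layout can spread")
    }
    tibble::tibble(
      breed = b,
      sire_id = sire_assign[ord],
      pen_id = rep(my_pens, length.out = nb))
  }))
  rows$room_id <- room_of_pen[match(rows$pen_id, pen_ids)]
  rows$animal_id <- sprintf("an%04d", seq_len(nrow(rows)))
  rows[, c("animal_id", "breed", "room_id", "pen_id", "sire_id")]
}

#' Simulate feeder visit records with known event structure
#'
#' For each animal, daily feed consumption is a per-animal linear growth
#' trend plus a pen effect, AR(1)-correlated daily noise, and (for a
#' random subset of animals) one multi-day intake-depression event.
#' Negative daily values are floored at zero and flagged in the truth.
#' Each observed day is split into 1 to `visits_max` feeder visits whose
#' intakes sum exactly to the daily value.
#'
#' @param config A [sim_config()] list.
#' @param metadata Cohort tibble from [simulate_cohort()].
#' @param seed Seed.
#' @return List with `visits` (tibble in the feed-cleaning dialect),
#'   `daily` (per-animal-day truth components) and `truth` (list with
#'   `events`, `floored`, and the per-animal trend parameters).
#' @export
simulate_feed_intake <- function(config = sim_config(),
                                 metadata, seed = 1) {
  set.seed(seed)
  ages <- config$age_start:config$age_end
  nd <- length(ages)
  pen_levels <- unique(metadata$pen_id)
  pen_eff <- setNames(rnorm(length(pen_levels), 0, config$pen_sd),
                      pen_levels)

  per_animal <- purrr::map(seq_len(nrow(metadata)), function(i) {
    a <- metadata[i, ]
    start <- rnorm(1, config$intake_start_mean, config$intake_start_sd)
    slope <- rnorm(1, config$growth_slope_mean, config$growth_slope_sd)
    innov_sd <- config$noise_sd * sqrt(1 - config$noise_phi^2)
    noise <- numeric(nd)
    noise[1] <- rnorm(1, 0, config$noise_sd)
    for (d in 2:nd) {
      noise[d] <- config$noise_phi * noise[d - 1] + rnorm(1, 0, innov_sd)
    }
    depression <- numeric(nd)
    event <- NULL
    if (runif(1) < config$event_prob) {
      durs <- config$event_duration[1]:config$event_duration[2]
      dur <- durs[sample.int(length(durs), 1)]
      if (dur <= nd) {
        s <- sample(seq_len(nd - dur + 1), 1)
        depth <- max(0, rnorm(1, config$event_depth_mean,
                              config$event_depth_sd))
        depression[s:(s + dur - 1)] <- depth
        event <- tibble::tibble(animal_id = a$animal_id,
                                start_age = ages[s],
                                end_age = ages[s + dur - 1], depth = depth)
      }
    }
    fcd_raw <- start + slope * (ages - config$age_start) +
      pen_eff[[a$pen_id]] + noise - depression
    floored <- fcd_raw < 0
    fcd <- pmax(fcd_raw, 0)
    missing <- runif(nd) < config$miss_prob
    list(daily = tibble::tibble(
      animal_id = a$animal_id, age_days = ages, fcd_true = fcd,
      depression = depression, missing = missing, floored = floored),
      event = event,
      params = tibble::tibble(animal_id = a$animal_id, intake_start = start,
                              slope = slope))
  })

  daily <- purrr::list_rbind(purrr::map(per_animal, "daily"))
  events <- purrr::list_rbind(purrr::compact(purrr::map(per_animal,
                                                        "event")))
  params <- purrr::list_rbind(purrr::map(per_animal, "params"))

  obs <- daily[!daily$missing, , drop = FALSE]
  k <- sample.int(config$visits_max, nrow(obs), replace = TRUE)
  idx <- rep(seq_len(nrow(obs)), k)
  w <- rexp(length(idx))
  wsum <- as.vector(rowsum(w, idx))
  visits <- tibble::tibble(
    animal_id = obs$animal_id[idx],
    age_days = obs$age_days[idx],
    intake_kg = obs$fcd_true[idx] * w / wsum[idx])
  visits <- dplyr::left_join(visits, metadata, by = "animal_id")
  visits <- visits[, c("animal_id", "pen_id", "room_id", "breed",
                       "sire_id", "age_days", "intake_kg")]
  list(visits = visits, daily = daily,
       truth = list(events = events, params = params, pen_eff = pen_eff))
}

scale_to_var <- function(x, v) {
  if (v <= 0 || length(x) < 2 || var(x) == 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(v / var(x))
}

#' Simulate ASV counts with a planted microbial effect
#'
#' Builds a latent per-animal log-composition (log-normal ASV baseline
#' plus animal noise), plants a microbial signal, and draws multinomial
#' counts at a sampled sequencing depth (a configurable fraction of
#' samples is planted below depth 700 to exercise the depth filter).
#'
#' Three signal modes:
#' * default: a latent indicator is constructed as
#'   `microbial + pen + sire + residual`, each component rescaled so its
#'   realised variance share matches the configured targets exactly; the
#'   microbial component is a linear combination of the latent CLR values
#'   of the informative ASVs.
#' * `indicator_values`: the supplied (externally computed) indicator is
#'   mixed into the first community factor's scores so that the share of
#'   indicator variance recoverable from composition is `effect_size`
#'   (default: the configured `m2`). Coupling through a community axis —
#'   rather than through each informative ASV independently — keeps the
#'   recoverable share calibrated: composition reveals the factor almost
#'   exactly, and the factor carries exactly that share of the indicator.
#' * `class_labels`: animals of the classes named in `class_effects` have
#'   their informative ASVs shifted by the given amounts, planting a
#'   class-specific compositional signature (e.g. only class `L`).
#'
#' @param config A [sim_config()] list.
#' @param metadata Cohort tibble.
#' @param seed Seed.
#' @param indicator_values Optional numeric vector aligned to `metadata`.
#' @param class_labels Optional factor/character aligned to `metadata`.
#' @param class_effects Named numeric vector of latent shifts per class
#'   (used with `class_labels`). Default `c(L = 1)`.
#' @param effect_size Variance share of the indicator carried by the
#'   coupled community factor in `indicator_values` mode; `NULL`
#'   (default) uses the configured `m2`.
#' @return List with `counts` (samples x ASVs integer matrix) and `truth`
#'   (informative ASV ids, effect vector, per-animal components, realised
#'   m2, planted low-depth sample ids).
#' @export
simulate_microbiome <- function(config = sim_config(), metadata, seed = 1,
                                indicator_values = NULL,
                                class_labels = NULL,
                                class_effects = c(L = 1),
                                effect_size = NULL) {
  set.seed(seed)
  n <- nrow(metadata)
  p <- config$n_asv
  asv_ids <- sprintf("asv%04d", seq_len(p))
  base <- rnorm(p, 0, config$base_log_sd)
  scores <- matrix(rnorm(n * config$n_factors), n, config$n_factors)
  loadings <- matrix(rnorm(p * config$n_factors, 0, config$factor_sd),
                     p, config$n_factors)
  if (!is.null(indicator_values)) {
    stopifnot(length(indicator_values) == n)
    share <- effect_size %||% config$m2
    stopifnot(share >= 0, share < 1)
    z <- as.vector(scale(indicator_values))
    scores[, 1] <- sqrt(share) * z + sqrt(1 - share) * scores[, 1]
  }
  latent <- scores %*% t(loadings) +
    matrix(rnorm(n * p, 0, config$animal_log_sd), n, p)
  dimnames(latent) <- list(metadata$animal_id, asv_ids)
  latent <- sweep(latent, 2, base, "+")
  n_info <- min(config$n_informative, p)
  informative <- if (!is.null(indicator_values) && n_info > 0) {
    # in coupling mode the informative ASVs are those expressing the
    # indicator-linked community factor most strongly
    sort(order(abs(loadings[, 1]), decreasing = TRUE)[seq_len(n_info)])
  } else if (n_info > 0) {
    sort(sample.int(p, n_info))
  } else integer(0)
  b <- if (n_info > 0) rnorm(n_info) else numeric(0)

  components <- NULL
  realized_m2 <- NA_real_
  if (!is.null(class_labels)) {
    stopifnot(length(class_labels) == n)
    for (cl in names(class_effects)) {
      hit <- which(as.character(class_labels) == cl)
      if (length(hit) > 0 && n_info > 0) {
        shift <- outer(rep(class_effects[[cl]], length(hit)), sign(b))
        latent[hit, informative] <- latent[hit, informative] + shift
      }
    }
  } else if (!is.null(indicator_values)) {
    # coupling already applied through the first factor's scores; record
    # the factor loadings of the informative ASVs as the effect vector
    if (n_info > 0) b <- loadings[informative, 1]
  } else {
    clr_latent <- latent - rowMeans(latent)
    m_comp <- if (n_info > 0) {
      as.vector(clr_latent[, informative, drop = FALSE] %*% b)
    } else rep(0, n)
    m_comp <- scale_to_var(m_comp, config$m2)
    pen_raw <- setNames(rnorm(dplyr::n_distinct(metadata$pen_id)),
                        unique(metadata$pen_id))[metadata$pen_id]
    pen_comp <- scale_to_var(unname(pen_raw), config$pen_share)
    sire_raw <- setNames(rnorm(dplyr::n_distinct(metadata$sire_id)),
                         unique(metadata$sire_id))[metadata$sire_id]
    sire_comp <- scale_to_var(unname(sire_raw), config$sire_share)
    resid_share <- 1 - config$m2 - config$pen_share - config$sire_share
    resid <- scale_to_var(rnorm(n), resid_share)
    indicator <- m_comp + pen_comp + sire_comp + resid
    vtot <- var(m_comp) + var(pen_comp) + var(sire_comp) + var(resid)
    realized_m2 <- if (vtot > 0) var(m_comp) / vtot else 0
    components <- tibble::tibble(
      animal_id = metadata$animal_id, microbial = m_comp,
      pen = pen_comp, sire = sire_comp, residual = resid,
      indicator = indicator)
  }

  depth <- round(rlnorm(n, config$depth_meanlog, config$depth_sdlog))
  depth <- pmax(depth, 800)
  n_low <- floor(config$low_depth_frac * n)
  low_ids <- character(0)
  if (n_low > 0) {
    li <- sample.int(n, n_low)
    depth[li] <- round(runif(n_low, 100, 699))
    low_ids <- metadata$animal_id[li]
  }
  counts <- t(vapply(seq_len(n), function(i) {
    pr <- exp(latent[i, ] - max(latent[i, ]))
    as.vector(rmultinom(1, depth[i], pr / sum(pr)))
  }, numeric(p)))
  dimnames(counts) <- list(metadata$animal_id, asv_ids)

  list(counts = counts,
       truth = list(informative = asv_ids[informative], effects = b,
                    components = components, realized_m2 = realized_m2,
                    depth = setNames(depth, metadata$animal_id),
                    low_depth_samples = low_ids))
}
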