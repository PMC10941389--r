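# Small fixture builders shared across test files.

toy_visits <- function() {
  tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 4),
    pen_id = rep(c("p1", "p2"), each = 4),
    room_id = "r1",
    breed = rep(c("B1", "B2"), each = 4),
    sire_id = rep(c("s1", "s2"), each = 4),
    age_days = c(100L, 100L, 101L, 103L, 100L, 101L, 102L, 103L),
    intake_kg = c(0.5, 0.7, 1.2, 1.1, 1.0, 1.1, 0.9, 1.2))
}

# Daily tibble for one animal from an fcd vector starting at `start_age`.
daily_from_vector <- function(fcd, start_age = 99, animal_id = "a1",
                              breed = "B1") {
  tibble::tibble(
    animal_id = animal_id, breed = breed, pen_id = "p1", room_id = "r1",
    sire_id = "s1",
    age_days = seq(start_age, by = 1, length.out = length(fcd)),
    fcd_kg = fcd, missing = is.na(fcd))
}

toy_counts <- function() {
  m <- matrix(c(10, 5, 0, 1,
                8, 2, 4, 0,
                3, 3, 3, 3,
                20, 0, 0, 0), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("s", 1:4), paste0("asv", 1:4))
  m
}

small_cohort_microbiome <- function(n = 120, n_asv = 150, m2 = 0.2,
                                    seed = 7, low_depth_frac = 0,
                                    n_informative = 20, ...) {
  cfg <- sim_config(n_animals = n, n_asv = n_asv,
                    n_informative = n_informative,
                    m2 = m2, low_depth_frac = low_depth_frac, ...)
  meta <- simulate_cohort(cfg, seed = seed)
  mb <- simulate_microbiome(cfg, meta, seed = seed + 1)
  list(cfg = cfg, meta = meta, mb = mb)
}
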