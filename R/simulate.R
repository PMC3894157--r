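#' Configuration for a synthetic plate-reader screen
#'
#' Bundles the growth-model and design parameters used by the plate and
#' library generators. Defaults describe a typical arrayed yeast screen:
#' 96-well plates read every 30 minutes, 3 biological replicates, 36
#' technical replicate wells per strain (12 per biological replicate), and
#' at least 4 wild-type reference wells plus 2 medium-only blank wells per
#' plate.
#'
#' The growth model is a three-parameter logistic with an explicit lag:
#' before `lag_wt` hours the culture sits at its inoculum density `od0`;
#' afterwards OD follows `K / (1 + ((K - od0)/od0) * exp(-r (t - lag)))`.
#' Plate-reader output is the blank (`blank_od`) plus the culture OD plus
#' additive Gaussian noise (`noise_sd`) clipped at zero. Biological
#' replicates differ by lognormal multipliers on rate and capacity with
#' coefficient of variation `cv_bio`.
#'
#' @param n_strains Number of library strains.
#' @param conditions Character vector of condition labels.
#' @param n_bio_reps Biological replicates per strain (default 3).
#' @param n_tech_reps Total technical replicate wells per strain, split
#'   evenly across biological replicates (default 36; must be divisible by
#'   `n_bio_reps`).
#' @param wells_per_plate Wells per plate (default 96).
#' @param n_wt_wells Wild-type reference wells per plate (default 4).
#' @param n_blank_wells Medium-only wells per plate (default 2).
#' @param t_max Duration of the read in hours (default 30).
#' @param dt Sampling interval in hours (default 0.5, i.e. every 30 min).
#' @param od0 Inoculum OD (default 0.02).
#' @param K_wt Wild-type carrying capacity in OD units (default 1.2).
#' @param r_wt Wild-type maximal specific growth rate in 1/h (default 0.4).
#' @param lag_wt Lag phase in hours (default 2).
#' @param blank_od Optical density of the medium (default 0.08).
#' @param noise_sd Additive OD measurement noise (default 0.005).
#' @param cv_bio Between-biological-replicate coefficient of variation of
#'   the lognormal culture multipliers (default 0.02).
#' @param lethal_threshold Max blank-subtracted OD below which a strain is
#'   called lethal (default 0.05).
#' @param seed Master seed; per-plate streams are derived from it by a
#'   stable hash of (condition, plate index).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 10, conditions = "YPD", n_tech_reps = 6)
sim_config <- function(n_strains,
                       conditions = "YPD",
                       n_bio_reps = 3,
                       n_tech_reps = 36,
                       wells_per_plate = 96,
                       n_wt_wells = 4,
                       n_blank_wells = 2,
                       t_max = 30,
                       dt = 0.5,
                       od0 = 0.02,
                       K_wt = 1.2,
                       r_wt = 0.4,
                       lag_wt = 2,
                       blank_od = 0.08,
                       noise_sd = 0.005,
                       cv_bio = 0.02,
                       lethal_threshold = 0.05,
                       seed = 1L) {
  assert_scalar_number(n_strains, "n_strains")
  assert_scalar_number(dt, "dt")
  assert_scalar_number(t_max, "t_max")
  assert_scalar_number(od0, "od0")
  assert_scalar_number(K_wt, "K_wt")
  assert_scalar_number(r_wt, "r_wt")
  assert_scalar_number(lag_wt, "lag_wt", positive = FALSE)
  assert_scalar_number(blank_od, "blank_od", positive = FALSE)
  assert_scalar_number(noise_sd, "noise_sd", positive = FALSE)
  assert_scalar_number(cv_bio, "cv_bio", positive = FALSE)
  if (n_tech_reps < 1) abort("`n_tech_reps` must be >= 1")
  if (n_tech_reps %% n_bio_reps != 0) {
    abort("`n_tech_reps` must be divisible by `n_bio_reps`")
  }
  if (n_wt_wells < 1) abort("every plate needs at least one wild-type well")
  if (noise_sd < 0 || cv_bio < 0) abort("noise parameters must be >= 0")
  if (length(conditions) < 1) abort("need at least one condition label")
  if (wells_per_plate <= n_wt_wells + n_blank_wells) {
    abort("`wells_per_plate` leaves no room for library strains")
  }
  structure(list(
    n_strains = as.integer(n_strains), conditions = as.character(conditions),
    n_bio_reps = as.integer(n_bio_reps), n_tech_reps = as.integer(n_tech_reps),
    wells_per_plate = as.integer(wells_per_plate),
    n_wt_wells = as.integer(n_wt_wells), n_blank_wells = as.integer(n_blank_wells),
    t_max = t_max, dt = dt, od0 = od0, K_wt = K_wt, r_wt = r_wt,
    lag_wt = lag_wt, blank_od = blank_od, noise_sd = noise_sd,
    cv_bio = cv_bio, lethal_threshold = lethal_threshold,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Closed-form lagged logistic growth curve
#'
#' Blank-free culture OD at times `t`: constant at `od0` until `lag`, then
#' logistic growth towards carrying capacity `K` at maximal specific rate
#' `r`. This is the generating model of [simulate_plate()] and doubles as
#' the analytic oracle for the parameter extractors.
#'
#' @param t Times in hours.
#' @param K Carrying capacity (OD units).
#' @param r Maximal specific growth rate (1/h).
#' @param lag Lag time in hours.
#' @param od0 Inoculum OD.
#' @return Numeric vector of ODs (no blank, no noise).
#' @export
logistic_od <- function(t, K, r, lag = 0, od0 = 0.02) {
  if (K <= od0) {
    return(rep(od0, length(t)))
  }
  out <- rep(od0, length(t))
  grow <- t >= lag
  a <- (K - od0) / od0
  out[grow] <- K / (1 + a * exp(-r * (t[grow] - lag)))
  out
}

#' Default library truth specification
#'
#' Effect classes planted in a synthetic deletion library and the fraction
#' of strains assigned to each (deterministically, by largest remainder).
#' Multipliers act on the wild-type rate (`effect_rate`) and capacity
#' (`effect_yield`). The 0.90 multipliers are the "strong" plants: at the
#' default `cv_bio = 0.02` they sit about five wild-type standard
#' deviations below 1, i.e. well past the sigma = -2 phenotype threshold.
#'
#' @return A tibble with columns `class`, `fraction`, `effect_rate`,
#'   `effect_yield`, `lethal`.
#' @export
default_truth_spec <- function() {
  tibble(
    class = c("null", "yield_down", "yield_up", "rate_down",
              "rate_up", "both_down", "lethal"),
    fraction = c(0.60, 0.10, 0.05, 0.10, 0.05, 0.05, 0.05),
    effect_rate = c(1, 1, 1, 0.90, 1.10, 0.95, 0),
    effect_yield = c(1, 0.90, 1.10, 1, 1, 0.95, 0),
    lethal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# true (noise-free) reader OD for one well
well_true_od <- function(times, config, strain, effect_rate, effect_yield,
                         lethal, mult_rate, mult_yield) {
  if (strain == "BLANK") {
    return(rep(config$blank_od, length(times)))
  }
  if (isTRUE(lethal) || effect_yield <= 0 || effect_rate <= 0) {
    return(config$blank_od + rep(config$od0, length(times)))
  }
  K <- config$K_wt * effect_yield * mult_yield
  r <- config$r_wt * effect_rate * mult_rate
  config$blank_od + logistic_od(times, K = K, r = r,
                                lag = config$lag_wt, od0 = config$od0)
}

#' Simulate one plate of OD600 reads
#'
#' Generates the reader output for a single plate: each well's lagged
#' logistic curve (strain-specific rate and capacity multipliers from the
#' truth table, optional per-culture biological multipliers from the
#' assignment table) plus i.i.d. Gaussian measurement noise clipped at
#' zero. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param assignments Tibble with columns `well`, `strain`, `bio_rep` and
#'   optionally `mult_rate`, `mult_yield` (biological culture multipliers,
#'   default 1). Reserved strain names: `"WT"` (wild type) and `"BLANK"`
#'   (medium only).
#' @param truth Optional strain truth tibble with columns `strain`,
#'   `effect_rate`, `effect_yield`, `lethal`; strains absent from it (other
#'   than WT/BLANK) are an error naming the offending well.
#' @param seed Integer seed for the noise stream.
#'
#' @return A list with `reads` (tibble `time_h`, `well`, `od`) and `map`
#'   (tibble `well`, `strain`, `bio_rep`).
#' @export
simulate_plate <- function(config, assignments, truth = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  assignments <- as_tibble(assignments)
  if (!all(c("well", "strain", "bio_rep") %in% names(assignments))) {
    abort("`assignments` needs columns well, strain, bio_rep")
  }
  if (anyDuplicated(assignments$well)) abort("duplicate wells in `assignments`")
  if (!any(assignments$strain == "WT")) {
    abort("every simulated plate must contain at least one WT well")
  }
  times <- seq(0, config$t_max, by = config$dt)
  if (max(times) < config$lag_wt) {
    abort("no growth phase sampled: t_max is shorter than the lag")
  }

  if (!"mult_rate" %in% names(assignments)) assignments$mult_rate <- 1
  if (!"mult_yield" %in% names(assignments)) assignments$mult_yield <- 1

  known <- c("WT", "BLANK", if (!is.null(truth)) truth$strain)
  unknown <- !(assignments$strain %in% known)
  if (any(unknown)) {
    abort(paste0("unknown strain '", assignments$strain[which(unknown)[1]],
                 "' in well ", assignments$well[which(unknown)[1]]))
  }

  lookup <- tibble(strain = "WT", effect_rate = 1, effect_yield = 1, lethal = FALSE)
  if (!is.null(truth)) {
    lookup <- bind_rows(lookup, as_tibble(truth)[, c("strain", "effect_rate",
                                                     "effect_yield", "lethal")])
  }
  ann <- dplyr::left_join(assignments, lookup, by = "strain")

  withr::with_seed(as.integer(seed) %% 2147483647L, {
    reads <- purrr::pmap(list(ann$strain, ann$effect_rate, ann$effect_yield,
                              ann$lethal, ann$mult_rate, ann$mult_yield, ann$well),
      function(strain, er, ey, lethal, mr, my, well) {
        mu <- well_true_od(times, config, strain, er, ey, lethal, mr, my)
        od <- pmax(0, mu + rnorm(length(times), sd = config$noise_sd))
        tibble(time_h = times, well = well, od = od)
      })
  })
  reads <- bind_rows(reads) |> arrange(.data$well, .data$time_h)
  list(reads = reads,
       map = assignments[, c("well", "strain", "bio_rep")])
}

#' Simulate a full deletion-library screen with known ground truth
#'
#' Builds the library truth table from a truth specification (fractions of
#' strains per effect class, assigned deterministically), optionally
#' constructs double-deletion strains whose fitness obeys the
#' multiplicative null `W_AB = W_A * W_B + epsilon` with planted epsilon,
#' then lays every condition x biological replicate out on 96-well plates
#' (each with wild-type and blank wells) and simulates all reads.
#'
#' Biological replication: each (strain, biological replicate, condition)
#' is one culture with its own lognormal rate and capacity multipliers
#' (CV `cv_bio`) shared by that culture's technical replicate wells; each
#' wild-type well carries an independent culture so the wild-type reference
#' distribution reflects biological variance.
#'
#' @param config A [sim_config()].
#' @param truth_spec Tibble as returned by [default_truth_spec()]; the
#'   `fraction` column must lie in \[0, 1\] and sum to 1.
#' @param n_pairs Number of double-deletion pairs to construct (default 0).
#' @param pair_epsilon Epsilon values planted in the pairs, recycled across
#'   pairs (default `c(0, -0.3)`); applied to both rate and yield relative
#'   fitness.
#' @param seed Master seed (defaults to `config$seed`).
#'
#' @return A list with
#'   * `truth`: tibble `strain`, `aa`, `family`, `class`, `effect_rate`,
#'     `effect_yield`, `lethal`;
#'   * `pairs`: tibble `gene_a`, `gene_b`, `double_strain`, `eps_rate`,
#'     `eps_yield` (zero rows when `n_pairs = 0`);
#'   * `reads`: tibble `condition`, `plate`, `time_h`, `well`, `od`;
#'   * `map`: tibble `condition`, `plate`, `well`, `strain`, `bio_rep`.
#' @export
simulate_library <- function(config, truth_spec = default_truth_spec(),
                             n_pairs = 0, pair_epsilon = c(0, -0.3),
                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  truth_spec <- as_tibble(truth_spec)
  if (any(truth_spec$fraction < 0 | truth_spec$fraction > 1) ||
      abs(sum(truth_spec$fraction) - 1) > 1e-8) {
    abort("truth_spec fractions must lie in [0, 1] and sum to 1")
  }

  n <- config$n_strains
  counts <- apportion(n, truth_spec$fraction)
  idx <- rep.int(seq_len(nrow(truth_spec)), counts)
  aa_pool <- LETTERS[1:20]
  truth <- tibble(
    strain = sprintf("g%03d", seq_len(n)),
    aa = aa_pool[((seq_len(n) - 1) %/% 3) %% 20 + 1],
    family = sprintf("%s%02d", aa_pool[((seq_len(n) - 1) %/% 3) %% 20 + 1],
                     ((seq_len(n) - 1) %/% 3) %/% 20 + 1),
    class = truth_spec$class[idx],
    effect_rate = truth_spec$effect_rate[idx],
    effect_yield = truth_spec$effect_yield[idx],
    lethal = truth_spec$lethal[idx]
  )

  pairs <- tibble(gene_a = character(), gene_b = character(),
                  double_strain = character(),
                  eps_rate = numeric(), eps_yield = numeric())
  if (n_pairs > 0) {
    viable <- truth$strain[!truth$lethal]
    if (length(viable) < 2 * n_pairs) {
      abort("not enough viable strains to build the requested pairs")
    }
    ga <- viable[seq_len(n_pairs) * 2 - 1]
    gb <- viable[seq_len(n_pairs) * 2]
    eps <- rep_len(pair_epsilon, n_pairs)
    pairs <- tibble(gene_a = ga, gene_b = gb,
                    double_strain = paste0(ga, ".", gb),
                    eps_rate = eps, eps_yield = eps)
    ta <- truth[match(ga, truth$strain), ]
    tb <- truth[match(gb, truth$strain), ]
    doubles <- tibble(
      strain = pairs$double_strain,
      aa = ta$aa, family = ta$family, class = "double",
      effect_rate = pmax(0, ta$effect_rate * tb$effect_rate + pairs$eps_rate),
      effect_yield = pmax(0, ta$effect_yield * tb$effect_yield + pairs$eps_yield),
      lethal = FALSE
    )
    doubles$lethal <- doubles$effect_yield * config$K_wt < config$lethal_threshold
    truth <- bind_rows(truth, doubles)
  }

  tech_per_bio <- config$n_tech_reps %/% config$n_bio_reps
  n_strain_wells <- config$wells_per_plate - config$n_wt_wells - config$n_blank_wells

  all_reads <- list()
  all_maps <- list()
  master <- as.integer(seed)

  for (cond in config$conditions) {
    # one culture per (strain, bio_rep) per condition
    withr::with_seed(hash_seed(master, cond, "cultures"), {
      cultures <- tidyr::expand_grid(strain = truth$strain,
                                     bio_rep = seq_len(config$n_bio_reps)) |>
        mutate(
          mult_rate = rlnorm(dplyr::n(), meanlog = -log(1 + config$cv_bio^2) / 2,
                             sdlog = sqrt(log(1 + config$cv_bio^2))),
          mult_yield = rlnorm(dplyr::n(), meanlog = -log(1 + config$cv_bio^2) / 2,
                              sdlog = sqrt(log(1 + config$cv_bio^2)))
        )
    })

    plate_no <- 0L
    for (b in seq_len(config$n_bio_reps)) {
      slots <- rep(truth$strain, each = tech_per_bio)
      n_plates <- ceiling(length(slots) / n_strain_wells)
      for (p in seq_len(n_plates)) {
        plate_no <- plate_no + 1L
        lo <- (p - 1) * n_strain_wells + 1
        hi <- min(p * n_strain_wells, length(slots))
        plate_strains <- slots[lo:hi]
        n_wells <- length(plate_strains) + config$n_wt_wells + config$n_blank_wells
        wells <- well_labels(n_wells)
        assignments <- tibble(
          well = wells,
          strain = c(rep("WT", config$n_wt_wells),
                     rep("BLANK", config$n_blank_wells),
                     plate_strains),
          bio_rep = b
        ) |>
          dplyr::left_join(dplyr::filter(cultures, .data$bio_rep == b),
                           by = c("strain", "bio_rep"))
        # each WT well is an independent isolate; blanks carry no culture
        wt_i <- which(assignments$strain == "WT")
        withr::with_seed(hash_seed(master, cond, plate_no, "wt"), {
          assignments$mult_rate[wt_i] <-
            rlnorm(length(wt_i), -log(1 + config$cv_bio^2) / 2,
                   sqrt(log(1 + config$cv_bio^2)))
          assignments$mult_yield[wt_i] <-
            rlnorm(length(wt_i), -log(1 + config$cv_bio^2) / 2,
                   sqrt(log(1 + config$cv_bio^2)))
        })
        assignments$mult_rate[is.na(assignments$mult_rate)] <- 1
        assignments$mult_yield[is.na(assignments$mult_yield)] <- 1

        sim <- simulate_plate(config, assignments, truth = truth,
                              seed = hash_seed(master, cond, plate_no))
        all_reads[[length(all_reads) + 1L]] <-
          mutate(sim$reads, condition = cond, plate = plate_no, .before = 1)
        all_maps[[length(all_maps) + 1L]] <-
          mutate(sim$map, condition = cond, plate = plate_no, .before = 1)
      }
    }
  }

  list(truth = truth, pairs = pairs,
       reads = bind_rows(all_reads), map = bind_rows(all_maps))
}

#' Simulate replicate fitness triples for double-deletion pairs
#'
#' Lightweight generator for epistasis validation: for each pair, true
#' single-mutant relative fitness values `w_a`, `w_b` and a planted
#' interaction `epsilon` define the true double fitness
#' `w_ab = w_a * w_b + epsilon`; each biological replicate observes all
#' three fitness values with independent lognormal noise of CV `cv_bio`.
#'
#' @param n_pairs Number of pairs.
#' @param epsilon Planted epsilon values, recycled across pairs.
#' @param w_range True single-mutant fitness values are drawn uniformly
#'   from this range (default `c(0.8, 1.0)`).
#' @param cv_bio Per-replicate measurement CV (default 0.02).
#' @param n_bio_reps Biological replicates (default 3).
#' @param seed Integer seed.
#' @return List with `replicates` (tibble `pair_id`, `gene_a`, `gene_b`,
#'   `bio_rep`, `w_a`, `w_b`, `w_ab`) and `truth` (tibble `pair_id`,
#'   `gene_a`, `gene_b`, `w_a_true`, `w_b_true`, `epsilon_true`).
#' @export
simulate_epistasis_pairs <- function(n_pairs, epsilon = c(0, -0.3),
                                     w_range = c(0.8, 1.0), cv_bio = 0.02,
                                     n_bio_reps = 3, seed = 1L) {
  if (n_pairs < 1) abort("`n_pairs` must be >= 1")
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    truth <- tibble(
      pair_id = seq_len(n_pairs),
      gene_a = sprintf("a%03d", seq_len(n_pairs)),
      gene_b = sprintf("b%03d", seq_len(n_pairs)),
      w_a_true = stats::runif(n_pairs, w_range[1], w_range[2]),
      w_b_true = stats::runif(n_pairs, w_range[1], w_range[2]),
      epsilon_true = rep_len(epsilon, n_pairs)
    )
    sdlog <- sqrt(log(1 + cv_bio^2))
    meanlog <- -log(1 + cv_bio^2) / 2
    replicates <- tidyr::expand_grid(truth, bio_rep = seq_len(n_bio_reps)) |>
      mutate(
        w_a = .data$w_a_true * rlnorm(dplyr::n(), meanlog, sdlog),
        w_b = .data$w_b_true * rlnorm(dplyr::n(), meanlog, sdlog),
        w_ab = pmax(0, .data$w_a_true * .data$w_b_true + .data$epsilon_true) *
          rlnorm(dplyr::n(), meanlog, sdlog)
      ) |>
      select("pair_id", "gene_a", "gene_b", "bio_rep", "w_a", "w_b", "w_ab")
  })
  list(replicates = replicates, truth = truth)
}
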