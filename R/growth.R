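#' Control parameters for growth-curve analysis
#'
#' @param smooth_window Running-median window for [preprocess_curve()]
#'   (odd, >= 1; default 3).
#' @param rate_window Number of consecutive points in the sliding
#'   log-slope windows (default 5).
#' @param detection_floor OD below which readings are treated as
#'   undetectable and excluded from rate fitting (default 0.01).
#' @param eps_floor Additive floor inside the log to avoid `log(0)`
#'   (default 1e-4).
#' @param deriv_frac Stationary-phase threshold: the plateau is the maximal
#'   suffix whose smoothed OD derivative stays at or below this fraction of
#'   the maximal derivative (default 0.05).
#' @param persistence Minimum number of points a plateau must hold
#'   (default 3).
#' @param lethal_threshold Max blank-subtracted OD below which the well is
#'   called lethal / no growth (default 0.05).
#' @param r2_min Minimum R^2 a sliding window must reach for its slope to
#'   be a rate candidate; excludes noise-dominated lag windows
#'   (default 0.97).
#' @param sat_frac Windows whose mean OD exceeds this fraction of the
#'   plateau estimate are excluded from rate fitting (default 0.8); within
#'   the retained windows the fitted log-slope is corrected for logistic
#'   saturation by `slope / (1 - mean(od)/K_hat)`.
#' @return A named list of class `growth_control`.
#' @export
growth_control <- function(smooth_window = 3, rate_window = 5,
                           detection_floor = 0.01, eps_floor = 1e-4,
                           deriv_frac = 0.05, persistence = 3,
                           lethal_threshold = 0.05, r2_min = 0.97,
                           sat_frac = 0.8) {
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("`smooth_window` must be odd and >= 1")
  }
  if (rate_window < 3) abort("`rate_window` must be >= 3")
  structure(list(smooth_window = as.integer(smooth_window),
                 rate_window = as.integer(rate_window),
                 detection_floor = detection_floor, eps_floor = eps_floor,
                 deriv_frac = deriv_frac, persistence = as.integer(persistence),
                 lethal_threshold = lethal_threshold, r2_min = r2_min,
                 sat_frac = sat_frac),
            class = "growth_control")
}

#' Construct a single growth curve
#'
#' @param well Well identifier.
#' @param times Strictly increasing times in hours (length >= 8).
#' @param od OD600 values, same length as `times`.
#' @param flags Character vector of quality flags.
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(well, times, od, flags = character()) {
  if (length(times) != length(od)) abort("times and od lengths differ")
  if (length(times) < 8) abort("a growth curve needs at least 8 points")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (anyNA(od)) abort("od contains missing values")
  structure(list(well = well, times = as.numeric(times), od = as.numeric(od),
                 flags = unique(flags)),
            class = "growth_curve")
}

#' Read a plate time-series table and its plate map
#'
#' The reads file is long-format CSV with columns `time_h`, `well`, `od`;
#' the map is CSV with columns `well`, `strain`, `bio_rep`. Reserved strain
#' names: `WT` (wild type) and `BLANK` (medium only). Blank wells are
#' routed to blank estimation, not to strains; wells named in the map but
#' absent from the reads are returned flagged `missing` rather than
#' fabricated.
#'
#' @param path Reads CSV path.
#' @param plate_map_path Plate-map CSV path.
#' @return A list with `curves` (tibble `well`, `strain`, `bio_rep`,
#'   `curve` list-column of [growth_curve()]s, `missing` flag),
#'   `blank_curves` (list of blank-well curves) and `map` (the plate map).
#' @export
read_plate_table <- function(path, plate_map_path) {
  reads <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "well", "od")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    abort(paste0("reads file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  map <- utils::read.csv(plate_map_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("well", "strain", "bio_rep"), names(map))
  if (length(miss) > 0) {
    abort(paste0("plate map lacks column(s): ", paste(miss, collapse = ", ")))
  }
  unmapped <- setdiff(unique(reads$well), map$well)
  if (length(unmapped) > 0) {
    abort(paste0("well(s) not in plate map: ", paste(unmapped, collapse = ", ")))
  }
  if (anyDuplicated(reads[, c("well", "time_h")])) {
    abort("duplicate (well, time) readings")
  }

  split_reads <- split(reads, reads$well)
  curves <- purrr::map(split_reads, function(df) {
    df <- df[order(df$time_h), ]
    if (any(diff(df$time_h) <= 0)) {
      abort(paste0("non-monotone time in well ", df$well[1]))
    }
    growth_curve(df$well[1], df$time_h, df$od)
  })

  map <- as_tibble(map)
  tab <- map |>
    mutate(missing = !.data$well %in% names(curves),
           curve = purrr::map(.data$well, function(w) curves[[w]]))
  list(
    curves = dplyr::filter(tab, .data$strain != "BLANK"),
    blank_curves = tab$curve[tab$strain == "BLANK" & !tab$missing],
    map = map
  )
}

#' Blank-subtract and smooth a growth curve
#'
#' Subtracts the blank OD, clips negative values to zero, and applies
#' running-median smoothing; the curve length is preserved. A curve whose
#' readings never exceed the blank is flagged `no_growth` (not an error).
#'
#' @param raw A [growth_curve()].
#' @param blank Blank OD to subtract.
#' @param smooth_window Odd running-median window (>= 1; 1 disables
#'   smoothing).
#' @return A preprocessed `growth_curve`.
#' @export
preprocess_curve <- function(raw, blank, smooth_window = 3) {
  stopifnot(inherits(raw, "growth_curve"))
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("`smooth_window` must be odd and >= 1")
  }
  flags <- raw$flags
  if (blank >= max(raw$od)) flags <- union(flags, "no_growth")
  od <- pmax(0, raw$od - blank)
  if (smooth_window > 1) {
    od <- as.numeric(runmed(od, k = min(smooth_window,
                                        2 * (length(od) %/% 2) - 1),
                            endrule = "median"))
  }
  growth_curve(raw$well, raw$times, od, flags)
}

# mean blank OD: pooled blank wells if available, else per-curve minimum of
# the first three readings
estimate_blank <- function(blank_curves, curve = NULL) {
  if (length(blank_curves) > 0) {
    mean(unlist(lapply(blank_curves, function(cv) cv$od)))
  } else if (!is.null(curve)) {
    min(curve$od[seq_len(min(3, length(curve$od)))])
  } else {
    0
  }
}

# sliding-window least-squares slopes of y on x; returns slopes, R^2 and
# window mean of `od` via cumulative sums (O(n))
window_slopes <- function(x, y, od, w) {
  n <- length(x)
  if (n < w) {
    return(NULL)
  }
  cs <- function(v) cumsum(v)
  sx <- cs(x); sy <- cs(y); sxx <- cs(x * x); sxy <- cs(x * y)
  syy <- cs(y * y); sod <- cs(od)
  win_sum <- function(s) s[w:n] - c(0, s)[seq_len(n - w + 1)]
  Sx <- win_sum(sx); Sy <- win_sum(sy); Sxx <- win_sum(sxx)
  Sxy <- win_sum(sxy); Syy <- win_sum(syy); Sod <- win_sum(sod)
  ssx <- Sxx - Sx^2 / w
  ssy <- Syy - Sy^2 / w
  sxy_c <- Sxy - Sx * Sy / w
  slope <- sxy_c / ssx
  r2 <- ifelse(ssy > 0, (sxy_c^2) / (ssx * ssy), 0)
  tibble(start = seq_len(n - w + 1), end = w:n,
         slope = slope, r2 = r2, mean_od = Sod / w)
}

#' Extract growth rate and growth yield from a preprocessed curve
#'
#' The maximal specific growth rate is estimated from sliding windows
#' (default 5 points) of the least-squares slope of `log(od + eps_floor)`
#' against time, restricted to detectable readings
#' (`od >= detection_floor`) and to windows whose log-linear fit reaches
#' `r2_min`. When a stationary plateau is detected, each window slope is
#' corrected for logistic saturation by `slope / (1 - mean(od)/K_hat)`
#' (exact for a logistic, where the instantaneous log-slope is
#' `r (1 - od/K)`), near-saturated windows (`mean(od) > sat_frac * K_hat`)
#' are excluded, and the rate is the median of the corrected window
#' slopes - under the logistic model every growth-phase window then
#' estimates the same maximal rate, so the median is both unbiased and
#' robust to reader noise. Without a plateau (curve still exponential at
#' the last read) the rate falls back to the maximum window slope.
#'
#' The growth yield is the mean OD over the stationary plateau: the
#' maximal suffix of time points whose smoothed derivative stays at or
#' below `deriv_frac` of its maximum (at least `persistence` points). If
#' the culture never reaches a plateau the yield falls back to `max(od)`
#' and the result is flagged `truncated`. A well whose maximum OD stays
#' below `lethal_threshold` is called lethal (rate and yield 0); fewer
#' detectable points than a window gives a no-growth result, never an
#' error.
#'
#' @param curve A preprocessed [growth_curve()].
#' @param control A [growth_control()].
#' @return A one-row tibble: `well`, `rate`, `yield`, `rate_t_start`,
#'   `rate_t_end`, `lethal`, `truncated`, `no_growth`.
#' @export
extract_growth_params <- function(curve, control = growth_control()) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times
  od <- curve$od
  n <- length(od)
  res <- tibble(well = curve$well, rate = 0, yield = 0,
                rate_t_start = NA_real_, rate_t_end = NA_real_,
                lethal = FALSE, truncated = FALSE, no_growth = FALSE)

  if (max(od) < control$lethal_threshold || "no_growth" %in% curve$flags) {
    res$lethal <- max(od) < control$lethal_threshold
    res$no_growth <- TRUE
    return(res)
  }

  # stationary plateau from a smoothed derivative: centred 5-point
  # least-squares slope of OD vs time (shorter one-sided windows at the
  # ends), median-filtered; violation gaps shorter than `persistence` are
  # closed so isolated noisy readings cannot break the plateau suffix
  d <- numeric(n)
  if (n >= 7) {
    wd <- 7L  # wider than the rate window: only low-frequency slope matters
    sl <- window_slopes(t, od, od, wd)$slope
    half <- wd %/% 2
    d[(half + 1):(n - half)] <- sl
    d[seq_len(half)] <- sl[1]
    d[(n - half + 1):n] <- sl[length(sl)]
    d <- as.numeric(runmed(d, 5, endrule = "median"))
  } else {
    d[2:(n - 1)] <- (od[3:n] - od[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    d[1] <- d[2]
    d[n] <- d[n - 1]
  }
  dmax <- max(d)
  K_hat <- NA_real_
  if (dmax > 0) {
    below <- d <= control$deriv_frac * dmax
    gaps <- rle(below)
    short_gap <- !gaps$values & gaps$lengths < control$persistence
    gaps$values[short_gap] <- TRUE
    below <- inverse.rle(gaps)
    run_end <- rev(cumprod(rev(below)))  # 1 for suffix members
    suffix <- which(run_end == 1)
    if (length(suffix) >= control$persistence) {
      res$yield <- mean(od[suffix])
      K_hat <- res$yield
    }
  }
  if (is.na(K_hat)) {
    res$yield <- max(od)
    res$truncated <- TRUE
  }

  # sliding-window log-slope over detectable readings
  keep <- od >= control$detection_floor
  runs <- rle(keep)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  best <- NULL
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < control$rate_window) next
    sel <- idx_start[i]:idx_end[i]
    wins <- window_slopes(t[sel], log(od[sel] + control$eps_floor), od[sel],
                          control$rate_window)
    if (is.null(wins)) next
    wins$start <- sel[wins$start]
    wins$end <- sel[wins$end]
    best <- if (is.null(best)) wins else bind_rows(best, wins)
  }
  if (is.null(best)) {
    res$no_growth <- TRUE
    return(res)
  }
  best <- dplyr::filter(best, .data$r2 >= control$r2_min)
  corrected <- !is.na(K_hat)
  if (corrected) {
    best <- dplyr::filter(best, .data$mean_od <= control$sat_frac * K_hat)
    best$slope <- best$slope / (1 - best$mean_od / K_hat)
  }
  best <- dplyr::filter(best, is.finite(.data$slope))
  if (nrow(best) == 0 || max(best$slope) <= 0) {
    res$no_growth <- nrow(best) == 0
    res$rate <- 0
    return(res)
  }
  top <- if (corrected) {
    best[which.min(abs(best$slope - median(best$slope))), ]
  } else {
    best[which.max(best$slope), ]
  }
  res$rate <- if (corrected) median(best$slope) else top$slope
  res$rate_t_start <- t[top$start]
  res$rate_t_end <- t[top$end]
  res
}

#' Fit growth parameters for every well of one or more plates
#'
#' Convenience wrapper: estimates the blank (pooled `BLANK` wells when
#' present, else per-well minimum of the first three readings),
#' preprocesses every mapped well and extracts growth parameters. Input
#' tables may carry `condition` and `plate` columns (as produced by
#' [simulate_library()]); blanks are estimated per plate.
#'
#' @param reads Long tibble `time_h`, `well`, `od` (+ optional `condition`,
#'   `plate`).
#' @param map Tibble `well`, `strain`, `bio_rep` (+ the same optional
#'   grouping columns).
#' @param control A [growth_control()].
#' @return Tibble with one row per mapped well: grouping columns, `well`,
#'   `strain`, `bio_rep`, `rate`, `yield`, `lethal`, `truncated`,
#'   `no_growth`, `missing`.
#' @export
fit_growth <- function(reads, map, control = growth_control()) {
  reads <- as_tibble(reads)
  map <- as_tibble(map)
  keys <- intersect(c("condition", "plate"), names(map))
  if (length(keys) == 0) {
    reads$..grp <- "plate"
    map$..grp <- "plate"
    keys <- "..grp"
  } else {
    stopifnot(all(keys %in% names(reads)))
  }
  map_split <- dplyr::group_split(dplyr::group_by(map, across(dplyr::all_of(keys))))
  reads_key <- do.call(paste, c(reads[keys], sep = "\r"))

  out <- purrr::map(map_split, function(m) {
    rk <- do.call(paste, c(m[1, keys, drop = FALSE], sep = "\r"))
    r <- reads[reads_key == rk, , drop = FALSE]
    plate_wells <- split(r[, c("time_h", "well", "od")], r$well)
    blanks <- m$well[m$strain == "BLANK"]
    blank_curves <- purrr::map(intersect(blanks, names(plate_wells)),
      function(w) {
        df <- plate_wells[[w]]
        growth_curve(w, df$time_h, df$od)
      })
    blank0 <- if (length(blank_curves) > 0) estimate_blank(blank_curves) else NA_real_

    m_strains <- m[m$strain != "BLANK", , drop = FALSE]
    rows <- purrr::map(seq_len(nrow(m_strains)), function(i) {
      w <- m_strains$well[i]
      base <- m_strains[i, c(keys, "well", "strain", "bio_rep")]
      if (!w %in% names(plate_wells)) {
        return(mutate(base, rate = NA_real_, yield = NA_real_,
                      lethal = FALSE, truncated = FALSE, no_growth = FALSE,
                      missing = TRUE))
      }
      df <- plate_wells[[w]]
      raw <- growth_curve(w, df$time_h, df$od)
      blank <- if (is.na(blank0)) estimate_blank(list(), raw) else blank0
      cur <- preprocess_curve(raw, blank, control$smooth_window)
      p <- extract_growth_params(cur, control)
      mutate(base, rate = p$rate, yield = p$yield, lethal = p$lethal,
             truncated = p$truncated, no_growth = p$no_growth,
             missing = FALSE)
    })
    bind_rows(rows)
  })
  out <- bind_rows(out)
  out[["..grp"]] <- NULL
  out
}

#' Normalise per-well growth parameters to the plate wild type
#'
#' Each well's rate and yield are divided by the mean rate and yield of
#' the non-lethal wild-type wells on the same plate; technical replicates
#' of a strain on one plate are then averaged to a single value per
#' (strain, biological replicate, plate), and values from multiple plates
#' of the same biological replicate are averaged again.
#'
#' @param params Per-well parameter tibble from [fit_growth()] (must
#'   contain `strain`, `bio_rep`, `rate`, `yield`; `condition`/`plate`
#'   optional).
#' @return Tibble `strain`, `condition`, `bio_rep`, `rel_rate`,
#'   `rel_yield`, `lethal`, `n_tech`. Wild-type rows are retained (their
#'   per-plate mean is 1 by construction); blank wells never appear.
#' @export
normalize_to_wildtype <- function(params) {
  params <- as_tibble(params)
  if (!"condition" %in% names(params)) params$condition <- "all"
  if (!"plate" %in% names(params)) params$plate <- 1L
  if (!"missing" %in% names(params)) params$missing <- FALSE
  params <- params[!params$missing, , drop = FALSE]

  wt <- params |>
    dplyr::filter(.data$strain == "WT") |>
    group_by(.data$condition, .data$plate) |>
    summarise(wt_rate = mean(.data$rate[!.data$lethal]),
              wt_yield = mean(.data$yield[!.data$lethal]),
              n_wt = sum(!.data$lethal), .groups = "drop")
  plates <- distinct(params, .data$condition, .data$plate)
  lacking <- dplyr::anti_join(plates, wt, by = c("condition", "plate"))
  if (nrow(lacking) > 0) {
    abort(paste0("plate lacks wild-type reference: plate ",
                 lacking$plate[1], " (", lacking$condition[1], ")"))
  }
  if (any(wt$n_wt == 0)) {
    bad <- wt[wt$n_wt == 0, ][1, ]
    abort(paste0("all wild-type wells lethal on plate ", bad$plate,
                 " (", bad$condition, ")"))
  }

  params |>
    inner_join(wt, by = c("condition", "plate")) |>
    mutate(rel_rate = .data$rate / .data$wt_rate,
           rel_yield = .data$yield / .data$wt_yield) |>
    group_by(.data$condition, .data$plate, .data$strain, .data$bio_rep) |>
    summarise(rel_rate = mean(.data$rel_rate),
              rel_yield = mean(.data$rel_yield),
              lethal = mean(.data$lethal) > 0.5,
              n_tech = dplyr::n(), .groups = "drop") |>
    group_by(.data$condition, .data$strain, .data$bio_rep) |>
    summarise(rel_rate = sum(.data$rel_rate * .data$n_tech) / sum(.data$n_tech),
              rel_yield = sum(.data$rel_yield * .data$n_tech) / sum(.data$n_tech),
              lethal = mean(.data$lethal) > 0.5,
              n_tech = sum(.data$n_tech), .groups = "drop") |>
    select("strain", "condition", "bio_rep", "rel_rate", "rel_yield",
           "lethal", "n_tech")
}

#' Per-well wild-type relative values
#'
#' Relative rate and yield of each individual non-lethal wild-type well
#' against its own plate's wild-type mean; these per-well values, pooled
#' across the plates of a condition, form the empirical wild-type
#' distribution used by [build_wt_reference()].
#'
#' @param params Per-well parameter tibble from [fit_growth()].
#' @return Long tibble `condition`, `plate`, `well`, `parameter`
#'   (`"rate"`/`"yield"`), `value`.
#' @export
wt_well_relatives <- function(params) {
  params <- as_tibble(params)
  if (!"condition" %in% names(params)) params$condition <- "all"
  if (!"plate" %in% names(params)) params$plate <- 1L
  if (!"missing" %in% names(params)) params$missing <- FALSE
  wt <- params |>
    dplyr::filter(.data$strain == "WT", !.data$missing, !.data$lethal)
  if (nrow(wt) == 0) abort("no non-lethal wild-type wells")
  wt |>
    group_by(.data$condition, .data$plate) |>
    mutate(rate = .data$rate / mean(.data$rate),
           yield = .data$yield / mean(.data$yield)) |>
    ungroup() |>
    tidyr::pivot_longer(c("rate", "yield"), names_to = "parameter",
                        values_to = "value") |>
    select("condition", "plate", "well", "parameter", "value")
}
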