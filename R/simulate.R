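# Synthetic lesion-annotation cohort generator.
#
# Counts are drawn negative-binomially (Poisson when the configured cell
# is at or below Poisson dispersion) from the per-severity profiles.
# Every designed eye must be recoverable by the grading engine, so each
# eye of a grade with a configuration requirement is assigned one
# guaranteed "route" (e.g. for severe NPDR: >20 hemorrhages per quadrant,
# a venous-beading zone spanning two quadrants, or a prominent IRMA), and
# the count sampler's mean is pre-compensated -- a deterministic
# fixed-point solve at configuration time -- so that post-guarantee
# cohort means still equal the configured profile means in expectation.

#' Cohort generator configuration
#'
#' @param eyes_per_level Integer vector of length 5: eyes to generate at
#'   ICDR levels 0-4.
#' @param profiles Severity profile table, see [severity_profiles()].
#' @param spatial_concentration Non-negative decay rate (per degree) of
#'   lesion-center density with angular distance from the fovea; 0 means
#'   uniform placement over the seven-field union.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param grader_error_rate Probability in `[0, 1]` that the simulated
#'   second grader's ICDR label is perturbed by one level.
#' @param peripheral_rate Expected number of extra lesions placed outside
#'   the seven-field union, as a fraction of the in-field count per type.
#' @param route_probs_severe Named probabilities (`H`, `VB`, `IRMA`)
#'   of the guaranteed severe-NPDR rule route.
#' @param route_probs_pdr Named probabilities (`NVE`, `NVD`, `PRH/VH`) of
#'   the guaranteed proliferative-DR lesion.
#' @param n_vertices Vertices per lesion polygon.
#' @param mm_per_degree Retinal scale used to size lesion polygons.
#' @param rules Grading thresholds, see [grading_rules()]; the generator
#'   uses the hemorrhage quadrant threshold and the IRMA prominence area.
#' @return A list of class `cohort_config` with a precomputed sampling
#'   plan per level.
#' @export
cohort_config <- function(eyes_per_level = c(10, 10, 10, 10, 10),
                          profiles = severity_profiles(),
                          spatial_concentration = 0.05,
                          seed = 1L,
                          grader_error_rate = 0.05,
                          peripheral_rate = 0.10,
                          route_probs_severe = c(H = 0.25, VB = 0.25, IRMA = 0.5),
                          route_probs_pdr = c(NVE = 0.5, NVD = 0.25, `PRH/VH` = 0.25),
                          n_vertices = 20L,
                          mm_per_degree = rq_mm_per_degree(),
                          rules = grading_rules()) {
  stopifnot(length(eyes_per_level) == 5, all(eyes_per_level >= 0))
  if (grader_error_rate < 0 || grader_error_rate > 1) {
    stop("grader_error_rate must be in [0, 1]")
  }
  if (spatial_concentration < 0) stop("spatial_concentration must be >= 0")
  rq_validate_profiles(profiles)
  route_probs_severe <- route_probs_severe / sum(route_probs_severe)
  route_probs_pdr <- route_probs_pdr / sum(route_probs_pdr)
  cfg <- list(
    eyes_per_level = as.integer(eyes_per_level),
    profiles = profiles,
    spatial_concentration = spatial_concentration,
    seed = as.integer(seed),
    grader_error_rate = grader_error_rate,
    peripheral_rate = peripheral_rate,
    route_probs_severe = route_probs_severe,
    route_probs_pdr = route_probs_pdr,
    n_vertices = as.integer(n_vertices),
    mm_per_degree = mm_per_degree,
    rules = rules
  )
  cfg$plans <- lapply(0:4, function(lev) rq_build_plan(cfg, lev))
  class(cfg) <- "cohort_config"
  cfg
}

# ---- count sampling plan ----------------------------------------------------

# Expected final count when the raw draw D ~ dist(mu) is transformed to
# min(max(D, gmin), cap) on route eyes (probability w) and min(D, cap)
# otherwise.
rq_expected_final <- function(mu, size, w, gmin, cap) {
  if (mu <= 0) return(w * min(gmin, cap))
  kmax <- if (is.finite(size)) {
    stats::qnbinom(1 - 1e-12, size = size, mu = mu)
  } else {
    stats::qpois(1 - 1e-12, lambda = mu)
  }
  kmax <- max(kmax, gmin, 10)
  k <- 0:kmax
  p <- if (is.finite(size)) {
    stats::dnbinom(k, size = size, mu = mu)
  } else {
    stats::dpois(k, lambda = mu)
  }
  base <- pmin(k, cap)
  routed <- pmin(pmax(k, gmin), cap)
  sum(p * ((1 - w) * base + w * routed))
}

# Solve for the sampler mean mu so that the post-guarantee expectation
# equals the configured target mean.
rq_solve_mu <- function(target, size, w, gmin, cap) {
  if (target <= 0) return(0)
  floor_val <- rq_expected_final(0, size, w, gmin, cap)
  if (floor_val > target + 1e-9) {
    stop(sprintf(
      "route probability %.3g with guaranteed count %d is infeasible for a configured mean of %.3g",
      w, gmin, target
    ))
  }
  if (w == 0 && !is.finite(cap)) return(target)
  f <- function(mu) rq_expected_final(mu, size, w, gmin, cap) - target
  hi <- max(target, 1)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

# Per-level sampling plan: one row per lesion type with the adjusted
# sampler mean, dispersion, route probability, guaranteed minimum and cap.
rq_build_plan <- function(cfg, level) {
  prof <- cfg$profiles[cfg$profiles$level == level, ]
  prof <- prof[match(rq_lesion_types(), prof$lesion_type), ]
  hthr <- cfg$rules$h_quadrant_threshold
  plan <- lapply(seq_len(nrow(prof)), function(i) {
    ty <- prof$lesion_type[i]
    m <- prof$mean_count[i]
    s <- prof$sd_count[i]
    size <- if (s^2 > m && m > 0) m^2 / (s^2 - m) else Inf # Inf => Poisson
    w <- 0; gmin <- 0L; cap <- Inf
    if (level == 1 && ty == "MA") {
      w <- 1; gmin <- 1L
    }
    if (level == 1 && ty != "MA") m <- 0 # mild NPDR: MAs only
    if (level == 2) {
      if (ty == "H") cap <- 4 * hthr # never enough for the 4-2-1 count rule
      rp <- rq_l2_route_probs(cfg)
      if (ty %in% names(rp)) {
        w <- rp[[ty]]; gmin <- 1L
      }
      if (ty %in% rq_pdr_types()) m <- 0 # no proliferative lesions
    }
    if (level == 3) {
      if (ty == "H") {
        w <- cfg$route_probs_severe[["H"]]
        gmin <- 4L * (hthr + 1L)
      }
      if (ty == "VB") {
        w <- cfg$route_probs_severe[["VB"]]; gmin <- 1L
      }
      if (ty == "IRMA") {
        w <- cfg$route_probs_severe[["IRMA"]]; gmin <- 1L
      }
      if (ty %in% rq_pdr_types()) m <- 0
    }
    if (level == 4 && ty %in% names(cfg$route_probs_pdr)) {
      w <- cfg$route_probs_pdr[[ty]]; gmin <- 1L
    }
    mu <- rq_solve_mu(m, size, w, gmin, cap)
    list(
      lesion_type = ty, target_mean = m, size = size, mu = mu,
      route_w = w, gmin = gmin, cap = cap,
      area_mean = prof$mean_area_per_lesion[i],
      area_sd = prof$sd_area_per_lesion[i]
    )
  })
  names(plan) <- prof$lesion_type
  plan
}

# level-2 guaranteed non-MA lesion: weighted between the available
# non-MA, non-proliferative types (defaults: H and HE)
rq_l2_route_probs <- function(cfg) {
  prof <- cfg$profiles[cfg$profiles$level == 2, ]
  cand <- prof[!(prof$lesion_type %in% c("MA", rq_pdr_types())) &
                 prof$mean_count > 0, ]
  if (!nrow(cand)) {
    stop("level-2 profile needs at least one non-MA lesion type with ",
         "positive mean count")
  }
  # restrict to the two dominant types to keep compensation local
  cand <- cand[order(-cand$mean_count), ][seq_len(min(2, nrow(cand))), ]
  stats::setNames(rep(1 / nrow(cand), nrow(cand)), cand$lesion_type)
}

rq_draw_count <- function(p, on_route) {
  d <- if (p$mu <= 0) 0L else if (is.finite(p$size)) {
    stats::rnbinom(1, size = p$size, mu = p$mu)
  } else {
    stats::rpois(1, lambda = p$mu)
  }
  if (on_route) d <- max(d, p$gmin)
  min(d, p$cap)
}

# ---- lesion placement -------------------------------------------------------

# sample n lesion-center chart positions: direction uniform, chart radius
# from an exponential(kappa) density truncated to [0, 70] degrees, kept
# when inside the field union with the requested margin (deg) and, if
# `quadrant` is given, inside that quadrant with the margin from both
# axes.
rq_sample_centers <- function(layout, n, kappa, margin = 0, quadrant = NA,
                              max_ecc = 70) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, n, 2)
  got <- 0
  tries <- 0
  while (got < n) {
    m <- max(64, 4 * (n - got))
    r <- if (kappa > 0) {
      u <- stats::runif(m)
      -log(1 - u * (1 - exp(-kappa * max_ecc))) / kappa
    } else {
      max_ecc * sqrt(stats::runif(m)) # area-uniform in the chart
    }
    phi <- stats::runif(m, 0, 2 * pi)
    pts <- cbind(r * cos(phi), r * sin(phi))
    d <- rq_angular_dist_min(layout, pts)
    ok <- d <= layout$field_radius_deg - margin
    if (!is.na(quadrant)) {
      rel <- sweep(pts, 2, layout$fovea_center)
      tc <- as.vector(rel %*% layout$temporal_dir)
      sc <- as.vector(rel %*% layout$superior_dir)
      sgn_t <- if (quadrant %in% c(1, 3)) 1 else -1
      sgn_s <- if (quadrant %in% c(1, 2)) 1 else -1
      ok <- ok & (sgn_t * tc > margin) & (sgn_s * sc > margin)
    }
    hits <- which(ok)
    if (length(hits)) {
      take <- hits[seq_len(min(length(hits), n - got))]
      out[(got + 1):(got + length(take)), ] <- pts[take, , drop = FALSE]
      got <- got + length(take)
    }
    tries <- tries + 1
    if (tries > 400) stop("lesion placement failed: margin too large for region")
  }
  out
}

# minimum angular distance (deg) from chart points to the 7 field centers
rq_angular_dist_min <- function(layout, chart) {
  xyz <- rq_chart_to_xyz(chart)
  d <- xyz %*% t(layout$centers_xyz)
  acos(pmin(1, pmax(-1, apply(d, 1, max)))) * 180 / pi
}

# build an elliptical lesion polygon (chart degrees) of target spherical
# area (mm^2), centered at `center`, with aspect ratio and orientation
rq_make_polygon <- function(center, area_mm2, mm_per_degree, n_vertices,
                            aspect = NULL, angle = NULL) {
  if (is.null(aspect)) aspect <- exp(stats::runif(1, 0, log(2.5)))
  if (is.null(angle)) angle <- stats::runif(1, 0, 2 * pi)
  ecc <- sqrt(sum(center^2)) * pi / 180
  sinc <- if (ecc < 1e-9) 1 else sin(ecc) / ecc
  a_chart <- area_mm2 / (mm_per_degree^2 * sinc) # target chart area (deg^2)
  # inscribed n-gon loses area relative to the ellipse; inflate axes
  poly_corr <- (n_vertices / (2 * pi)) * sin(2 * pi / n_vertices)
  ab <- a_chart / (pi * poly_corr)
  a <- sqrt(ab * aspect)
  b <- sqrt(ab / aspect)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ex <- a * cos(t); ey <- b * sin(t)
  rot <- cbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  v <- cbind(ex, ey) %*% t(rot)
  cbind(lon = center[1] + v[, 1], lat = center[2] + v[, 2])
}

rq_poly_brad <- function(area_mm2, mm_per_degree, aspect = 2.5) {
  # conservative bounding radius in degrees for a lesion of given area
  sqrt(area_mm2 / (pi * mm_per_degree^2) * aspect) * 1.1
}

# ---- eye generation ---------------------------------------------------------

rq_draw_areas <- function(n, mean_a, sd_a) {
  if (n == 0) return(numeric(0))
  if (mean_a <= 0) return(rep(0.005, n)) # fallback for unspecified areas
  if (sd_a <= 0) return(rep(mean_a, n))
  sdlog2 <- log(1 + (sd_a / mean_a)^2)
  stats::rlnorm(n, meanlog = log(mean_a) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate one synthetic eye at a designed ICDR level
#'
#' Draws lesion counts and per-lesion areas from the configured profiles,
#' places lesion polygons over the seven-field union with central
#' weighting, and enforces the designed grade constructively (see the
#' package vignette). Uses the current RNG state; seed via
#' [generate_cohort()] for reproducibility.
#'
#' @param level Designed ICDR level (0-4).
#' @param config A [cohort_config()].
#' @param eye_id Identifier for the eye.
#' @return An object of class `eye_record`.
#' @export
generate_eye <- function(level, config = cohort_config(), eye_id = "eye1") {
  if (!level %in% 0:4) stop("unknown ICDR level: ", level)
  plan <- config$plans[[level + 1]]
  mmd <- config$mm_per_degree
  rules <- config$rules
  laterality <- sample(c("OD", "OS"), 1)
  sep <- stats::rnorm(1, 15.5, 0.5)
  disc <- c(if (laterality == "OD") -sep else sep, stats::rnorm(1, 1.5, 0.5))
  layout <- build_field_layout(disc, c(0, 0), laterality,
                               mm_per_degree = mmd)
  lesions <- list()
  add_lesion <- function(ty, poly) {
    lesions[[length(lesions) + 1]] <<- list(lesion_type = ty, poly = poly)
  }
  if (level > 0) {
    # choose the guaranteed rule route for this eye
    route <- switch(as.character(level),
      "1" = "MA",
      "2" = sample(names(rq_l2_route_probs(config)), 1,
                   prob = rq_l2_route_probs(config)),
      "3" = sample(names(config$route_probs_severe), 1,
                   prob = config$route_probs_severe),
      "4" = sample(names(config$route_probs_pdr), 1,
                   prob = config$route_probs_pdr)
    )
    kappa <- config$spatial_concentration
    hthr <- rules$h_quadrant_threshold
    for (ty in rq_lesion_types()) {
      p <- plan[[ty]]
      on_route <- identical(ty, route)
      n <- rq_draw_count(p, on_route)
      if (n == 0) next
      areas <- rq_draw_areas(n, p$area_mean, p$area_sd)
      # IRMA prominence handling
      if (ty == "IRMA") {
        if (level == 2) areas <- pmin(areas, 0.8 * rules$irma_prominence_mm2)
        if (level == 3 && on_route) {
          areas[1] <- max(areas[1], 2 * rules$irma_prominence_mm2)
        }
      }
      if (ty == "H" && (level == 2 || (level == 3 && on_route))) {
        # quadrant-controlled hemorrhages: quotas <= thr at level 2,
        # quotas > thr at severe on the hemorrhage route
        quota <- rq_h_quotas(n, level, hthr)
        idx <- 1
        for (q in 1:4) {
          if (quota[q] == 0) next
          br <- rq_poly_brad(max(areas[idx:(idx + quota[q] - 1)]), mmd)
          ctr <- rq_sample_centers(layout, quota[q], kappa,
                                   margin = min(br + 0.3, 6), quadrant = q)
          for (j in seq_len(quota[q])) {
            add_lesion(ty, rq_make_polygon(ctr[j, ], areas[idx], mmd,
                                           config$n_vertices))
            idx <- idx + 1
          }
        }
        next
      }
      n_guaranteed <- if (on_route && ty != "H") 1L else 0L
      if (n_guaranteed) {
        ar <- areas[1]
        br <- rq_poly_brad(ar, mmd, aspect = if (ty == "VB") 6 else 2.5)
        if (ty == "VB" && level >= 3) {
          # beading zone spanning two quadrants: center on the superior
          # axis, elongated across it
          ctr <- rq_sample_centers(layout, 1, kappa, margin = min(br + 0.5, 8))
          rel <- ctr - layout$fovea_center
          tc <- sum(rel * layout$temporal_dir)
          ctr <- layout$fovea_center + tc * layout$temporal_dir +
            0 * layout$superior_dir # project onto the temporal axis
          if (rq_angular_dist_min(layout, rbind(ctr)) >
              layout$field_radius_deg - br - 0.5) {
            ctr <- layout$fovea_center + 10 * layout$temporal_dir
          }
          ang <- atan2(layout$superior_dir[2], layout$superior_dir[1])
          add_lesion(ty, rq_make_polygon(as.numeric(ctr), ar, mmd,
                                         config$n_vertices, aspect = 6,
                                         angle = ang))
        } else if (ty == "NVD") {
          ctr <- layout$disc_center + stats::rnorm(2, 0, 1)
          add_lesion(ty, rq_make_polygon(ctr, ar, mmd, config$n_vertices))
        } else {
          ctr <- rq_sample_centers(layout, 1, kappa, margin = min(br + 0.3, 8))
          add_lesion(ty, rq_make_polygon(as.numeric(ctr), ar, mmd,
                                         config$n_vertices))
        }
      }
      n_free <- n - n_guaranteed
      if (n_free > 0) {
        ctr <- if (ty == "NVD") {
          cbind(layout$disc_center[1] + stats::rnorm(n_free, 0, 1.5),
                layout$disc_center[2] + stats::rnorm(n_free, 0, 1.5))
        } else if (ty == "VB" && level == 2) {
          q <- sample(1:4, 1)
          br <- rq_poly_brad(max(areas), mmd, aspect = 6)
          rq_sample_centers(layout, n_free, kappa, margin = min(br + 0.3, 6),
                            quadrant = q)
        } else {
          rq_sample_centers(layout, n_free, kappa)
        }
        for (j in seq_len(n_free)) {
          add_lesion(ty, rq_make_polygon(
            ctr[j, ], areas[n_guaranteed + j], mmd, config$n_vertices,
            aspect = if (ty %in% c("VB", "VL")) 6 else NULL
          ))
        }
      }
      # peripheral lesions outside the seven-field union
      n_out <- stats::rpois(1, config$peripheral_rate * n)
      if (n_out > 0) {
        r <- stats::runif(n_out, 55, 85)
        phi <- stats::runif(n_out, 0, 2 * pi)
        aro <- rq_draw_areas(n_out, p$area_mean, p$area_sd)
        for (j in seq_len(n_out)) {
          add_lesion(ty, rq_make_polygon(c(r[j] * cos(phi[j]),
                                           r[j] * sin(phi[j])),
                                         aro[j], mmd, config$n_vertices))
        }
      }
    }
  }
  lesion_tbl <- if (length(lesions)) {
    tibble::tibble(
      lesion_id = seq_along(lesions),
      lesion_type = vapply(lesions, `[[`, "", "lesion_type"),
      poly = lapply(lesions, `[[`, "poly")
    )
  } else {
    tibble::tibble(lesion_id = integer(0), lesion_type = character(0),
                   poly = list())
  }
  structure(
    list(
      eye_id = eye_id,
      laterality = laterality,
      disc_center = disc,
      fovea_center = c(0, 0),
      flags = list(poor_quality = FALSE, rvo = FALSE, interfering = FALSE,
                   questionable = FALSE, non_dr_abnormality = FALSE),
      lesions = lesion_tbl,
      designed_icdr = level
    ),
    class = "eye_record"
  )
}

# hemorrhage quadrant quotas: at level 2 each quadrant stays at or below
# the threshold; at severe (hemorrhage route) every quadrant exceeds it
rq_h_quotas <- function(n, level, thr) {
  if (level == 2) {
    quota <- rep(0L, 4)
    slots <- sample(rep(1:4, thr))[seq_len(min(n, 4 * thr))]
    for (q in 1:4) quota[q] <- sum(slots == q)
    quota
  } else {
    base <- rep(thr + 1L, 4)
    extra <- n - sum(base)
    if (extra > 0) {
      add <- tabulate(sample(1:4, extra, replace = TRUE), 4)
      base <- base + add
    }
    base
  }
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("eye %s (%s), designed ICDR %s, %d lesions\n",
              x$eye_id, x$laterality,
              if (is.null(x$designed_icdr)) "?" else x$designed_icdr,
              nrow(x$lesions)))
  if (nrow(x$lesions)) print(table(x$lesions$lesion_type))
  invisible(x)
}

#' Generate a synthetic cohort with designed-truth records
#'
#' @param config A [cohort_config()].
#' @return A list with `eyes` (list of `eye_record`) and `truth` (tibble
#'   with `eye_id`, `designed_icdr`, `designed_aa_level`, `grader2_icdr`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  eyes <- list()
  truth <- list()
  aa_map <- list(`0` = "10", `1` = "20", `2` = c("35", "43", "47"),
                 `3` = c("53", "53E"), `4` = c("61", "65", "71/75"))
  i <- 0
  for (lev in 0:4) {
    for (k in seq_len(config$eyes_per_level[lev + 1])) {
      i <- i + 1
      id <- sprintf("eye%04d", i)
      eye <- generate_eye(lev, config, eye_id = id)
      g2 <- lev
      if (stats::runif(1) < config$grader_error_rate) {
        g2 <- if (lev == 0) 1L else if (lev == 4) 3L else {
          lev + sample(c(-1L, 1L), 1)
        }
      }
      opts <- aa_map[[as.character(lev)]]
      truth[[i]] <- tibble::tibble(
        eye_id = id, designed_icdr = lev,
        designed_aa_level = if (length(opts) > 1) sample(opts, 1) else opts,
        grader2_icdr = g2
      )
      eyes[[i]] <- eye
    }
  }
  list(eyes = eyes, truth = dplyr::bind_rows(truth))
}

#' Flag randomly chosen eyes with exclusion reasons
#'
#' Marks the requested numbers of distinct eyes as poor quality, affected
#' by retinal vein occlusion, or carrying a pathology that interferes
#' with DR assessment. All other eyes are left unflagged.
#'
#' @param eyes List of `eye_record`s.
#' @param n_poor_quality,n_rvo,n_interfering Counts of eyes to flag.
#' @return The eye list with flags set.
#' @export
inject_exclusions <- function(eyes, n_poor_quality, n_rvo, n_interfering) {
  ntot <- n_poor_quality + n_rvo + n_interfering
  if (ntot > length(eyes)) stop("exclusion counts exceed cohort size")
  if (ntot == 0) return(eyes)
  pick <- sample(seq_along(eyes), ntot)
  reasons <- rep(c("poor_quality", "rvo", "interfering"),
                 c(n_poor_quality, n_rvo, n_interfering))
  for (j in seq_along(pick)) {
    eyes[[pick[j]]]$flags[[reasons[j]]] <- TRUE
  }
  eyes
}
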