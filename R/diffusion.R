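# Unwrapped centroid track of one molecule: minimum-image accumulation of
# frame-to-frame centroid displacements (valid while per-frame steps stay
# below half the box).
unwrapped_centroids <- function(trajectory, molecule) {
  st <- trajectory$structure
  rows <- which(st$molecule_id == molecule)
  if (length(rows) == 0) abort("no such molecule")
  box <- trajectory$box
  cents <- t(vapply(trajectory$coords, function(fr) {
    colMeans(fr[rows, , drop = FALSE])
  }, numeric(3)))
  if (is.null(box)) return(cents)
  steps <- diff(cents)
  steps <- steps - rep(box, each = nrow(steps)) *
    round(steps / rep(box, each = nrow(steps)))
  rbind(cents[1, , drop = FALSE],
        sweep(apply(steps, 2, cumsum), 2, cents[1, ], `+`))
}

# pooled MSD over molecules and time origins
msd_curve <- function(tracks, max_lag) {
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(L) {
    acc <- 0; npairs <- 0
    for (tr in tracks) {
      nf <- nrow(tr)
      if (nf <= L) next
      d <- tr[(L + 1):nf, , drop = FALSE] - tr[1:(nf - L), , drop = FALSE]
      acc <- acc + sum(d^2)
      npairs <- npairs + (nf - L)
    }
    acc / npairs
  }, numeric(1))
  tibble(lag = lags, msd = msd)
}

#' Translational diffusion from mean squared displacement
#'
#' Unwraps the molecule centroids, computes the time-origin-averaged MSD,
#' and fits MSD(tau) = 6 D tau + b by least squares over the chosen lag
#' window. With `mode = "pooled"` one MSD curve is accumulated over all
#' requested molecules (one fit); `mode = "per_molecule"` fits each
#' molecule separately and averages the estimates.
#'
#' @param trajectory A `biomass_trajectory` (>= 10 frames). Wrapped
#'   coordinates require a box for unwrapping.
#' @param molecules Molecule ids; default all molecules.
#' @param fit_window Length-2 integer vector: lag range (frames) for the
#'   linear fit.
#' @param mode `"pooled"` or `"per_molecule"`.
#' @return A `diffusion_estimate`: list with `d` (cm^2/s), `se`, `msd`
#'   (tibble: lag in frames, msd in A^2), `kind = "translational"`.
#' @export
translational_diffusion <- function(trajectory, molecules = NULL,
                                    fit_window = c(1, 20),
                                    mode = c("pooled", "per_molecule")) {
  stopifnot(inherits(trajectory, "biomass_trajectory"))
  mode <- match.arg(mode)
  nf <- n_frames(trajectory)
  if (nf < 10) abort("need at least 10 frames")
  if (fit_window[2] >= nf) abort("fit window exceeds available lags")
  molecules <- molecules %||% unique(trajectory$structure$molecule_id)
  tracks <- lapply(molecules, function(m) unwrapped_centroids(trajectory, m))
  dt <- trajectory$dt
  fit_one <- function(curve) {
    w <- curve[curve$lag >= fit_window[1] & curve$lag <= fit_window[2], ]
    fit <- lm(msd ~ lag, data = w)
    slope_a2_ns <- unname(coef(fit)[2]) / dt           # A^2 per ns
    se <- summary(fit)$coefficients[2, 2] / dt
    c(d = slope_a2_ns / 6 / CM2S_TO_A2NS, se = se / 6 / CM2S_TO_A2NS)
  }
  max_lag <- min(nf - 1, max(fit_window[2], 20))
  if (mode == "pooled") {
    curve <- msd_curve(tracks, max_lag)
    est <- fit_one(curve)
  } else {
    per <- vapply(tracks, function(tr) fit_one(msd_curve(list(tr), max_lag)),
                  numeric(2))
    est <- c(d = mean(per["d", ]),
             se = sd(per["d", ]) / sqrt(ncol(per)))
    curve <- msd_curve(tracks, max_lag)
  }
  structure(list(d = max(0, unname(est["d"])), se = unname(est["se"]),
                 msd = curve, fit_window = fit_window, mode = mode,
                 dt = dt, n_molecules = length(molecules),
                 kind = "translational"),
            class = "diffusion_estimate")
}

# body orientation per frame by Kabsch fit to frame 1; returns unit vectors
# tracking the frame-1 principal axis
orientation_track <- function(trajectory, molecule) {
  st <- trajectory$structure
  rows <- which(st$molecule_id == molecule)
  if (length(rows) < 3) abort("molecule needs at least 3 atoms")
  ref <- trajectory$coords[[1]][rows, , drop = FALSE]
  ref <- sweep(ref, 2, colMeans(ref))
  sv0 <- svd(ref)
  if (sv0$d[2] < 1e-8 * sv0$d[1]) {
    abort("molecule is (near-)linear: rotational diffusion of its axis is not identifiable")
  }
  axis0 <- sv0$v[, 1]
  t(vapply(trajectory$coords, function(fr) {
    cur <- fr[rows, , drop = FALSE]
    cur <- sweep(cur, 2, colMeans(cur))
    H <- crossprod(ref, cur)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    as.numeric(R %*% axis0)
  }, numeric(3)))
}

#' Rotational diffusion from angular mean squared displacement
#'
#' Tracks a body-fixed axis of the molecule through every frame (rigid-body
#' superposition onto the first frame), accumulates the mean squared
#' angular displacement of that axis over lag, and fits
#' MSAD(tau) = 4 D_rot tau in the small-angle regime.
#'
#' @param trajectory A `biomass_trajectory`.
#' @param molecules Molecule ids; default all.
#' @param fit_window Lag range (frames) for the fit.
#' @param mode `"pooled"` or `"per_molecule"`.
#' @return A `diffusion_estimate` with `d` in rad^2/s and
#'   `kind = "rotational"`.
#' @export
rotational_diffusion <- function(trajectory, molecules = NULL,
                                 fit_window = c(1, 20),
                                 mode = c("pooled", "per_molecule")) {
  stopifnot(inherits(trajectory, "biomass_trajectory"))
  mode <- match.arg(mode)
  nf <- n_frames(trajectory)
  if (nf < 10) abort("need at least 10 frames")
  if (fit_window[2] >= nf) abort("fit window exceeds available lags")
  molecules <- molecules %||% unique(trajectory$structure$molecule_id)
  tracks <- lapply(molecules, function(m) orientation_track(trajectory, m))
  dt_s <- trajectory$dt * 1e-9
  max_lag <- min(nf - 1, max(fit_window[2], 20))
  angular_curve <- function(trs) {
    lags <- seq_len(max_lag)
    msad <- vapply(lags, function(L) {
      acc <- 0; npairs <- 0
      for (tr in trs) {
        nf_i <- nrow(tr)
        if (nf_i <= L) next
        dots <- rowSums(tr[(L + 1):nf_i, , drop = FALSE] *
                          tr[1:(nf_i - L), , drop = FALSE])
        acc <- acc + sum(acos(pmin(1, pmax(-1, dots)))^2)
        npairs <- npairs + (nf_i - L)
      }
      acc / npairs
    }, numeric(1))
    tibble(lag = lags, msad = msad)
  }
  fit_one <- function(curve) {
    w <- curve[curve$lag >= fit_window[1] & curve$lag <= fit_window[2], ]
    fit <- lm(msad ~ lag, data = w)
    slope <- unname(coef(fit)[2]) / dt_s          # rad^2 per s
    se <- summary(fit)$coefficients[2, 2] / dt_s
    c(d = slope / 4, se = se / 4)
  }
  if (mode == "pooled") {
    curve <- angular_curve(tracks)
    est <- fit_one(curve)
  } else {
    per <- vapply(tracks, function(tr) fit_one(angular_curve(list(tr))),
                  numeric(2))
    est <- c(d = mean(per["d", ]), se = sd(per["d", ]) / sqrt(ncol(per)))
    curve <- angular_curve(tracks)
  }
  structure(list(d = max(0, unname(est["d"])), se = unname(est["se"]),
                 msd = curve, fit_window = fit_window, mode = mode,
                 dt = trajectory$dt, n_molecules = length(molecules),
                 kind = "rotational"),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  unit <- if (x$kind == "translational") "cm^2/s" else "rad^2/s"
  cat(sprintf("<diffusion_estimate> %s D = %.3g %s (se %.2g), %s fit over lags %d-%d\n",
              x$kind, x$d, unit, x$se, x$mode,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble(term = paste0("d_", substr(x$kind, 1, 5)),
         estimate = x$d, std.error = x$se)
}

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(d = x$d, se = x$se, kind = x$kind, mode = x$mode,
         n_molecules = x$n_molecules, dt_ns = x$dt,
         lag_min = x$fit_window[1], lag_max = x$fit_window[2])
}
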