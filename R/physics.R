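# 511-keV photon physics shared by the Monte-Carlo transport and the
# analytic single-scatter simulation. Energies in keV; m_e c^2 = 511.

ELECTRON_REST <- 511

# Klein-Nishina differential cross-section in the scattering angle,
# unnormalized (constant factors dropped): used both as the MC sampling
# density over the in-plane deflection angle and as the SSS angular weight.
kn_diff <- function(theta, energy = ELECTRON_REST) {
  a <- energy / ELECTRON_REST
  r <- 1 / (1 + a * (1 - cos(theta)))  # E'/E
  r^2 * (r + 1 / r - sin(theta)^2)
}

# total Klein-Nishina cross-section (per electron, arbitrary units),
# closed form; used for the energy scaling of the attenuation coefficient
kn_total <- function(energy) {
  a <- energy / ELECTRON_REST
  (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
}

# water-like photoelectric weight relative to Compton at 511 keV (~0.2%),
# scaling as E^-3; only matters for low-energy multiply-scattered photons
pe_weight <- function(energy, c_pe = 0.002) c_pe * (ELECTRON_REST / energy)^3

# scaling of the 511-keV linear attenuation coefficient to energy E
mu_energy_scale <- function(energy) {
  (kn_total(energy) / kn_total(ELECTRON_REST) + pe_weight(energy)) /
    (1 + pe_weight(ELECTRON_REST))
}

# probability that an interaction is Compton scattering (vs photoelectric)
compton_fraction <- function(energy) {
  kc <- kn_total(energy) / kn_total(ELECTRON_REST)
  kc / (kc + pe_weight(energy))
}

# scattered photon energy after deflection theta
compton_energy <- function(theta, energy = ELECTRON_REST) {
  energy / (1 + energy / ELECTRON_REST * (1 - cos(theta)))
}

# probability that a photon of true energy E, blurred with fractional FWHM
# resolution, is recorded inside the energy window
window_acceptance <- function(energy, geometry) {
  sigma <- geometry$energy_resolution_fwhm * energy / (2 * sqrt(2 * log(2)))
  stats::pnorm((geometry$energy_window[2] - energy) / sigma) -
    stats::pnorm((geometry$energy_window[1] - energy) / sigma)
}

# vectorized rejection sampler for the in-plane Compton deflection angle,
# density proportional to kn_diff(theta, E) on (-pi, pi]
sample_kn_angle <- function(energy) {
  n <- length(energy)
  out <- numeric(n)
  todo <- seq_len(n)
  # kn_diff is maximal at theta = 0 where it equals 2 (r = 1)
  fmax <- 2
  while (length(todo)) {
    th <- stats::runif(length(todo), -pi, pi)
    acc <- stats::runif(length(todo)) * fmax <= kn_diff(th, energy[todo])
    out[todo[acc]] <- th[acc]
    todo <- todo[!acc]
  }
  out
}

# bilinear sampling of a 2-D field at mm coordinates (zero outside)
sample_bilinear <- function(field, x, y, voxel, x0, y0) {
  n1 <- nrow(field); n2 <- ncol(field)
  fx <- (x - x0) / voxel + 1
  fy <- (y - y0) / voxel + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  out <- numeric(length(x))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy)
    idx <- ii[ok] + (jj[ok] - 1) * n1
    out[ok] <- out[ok] + w[ok] * field[idx]
  }
  out
}

# sinogram bin index (radial, angle) for the line through points A and B;
# returns NA for lines outside the radial range
lor_bins <- function(ax, ay, bx, by, geometry) {
  na <- geometry$n_angles; nr <- geometry$n_radial
  dphi <- pi / na
  phi <- atan2(by - ay, bx - ax) + pi / 2
  phi <- phi %% pi
  j <- round(phi / dphi) %% na          # 0-based angle bin
  phib <- j * dphi
  s <- ax * cos(phib) + ay * sin(phib)
  k <- round(s / geometry$radial_width + (nr + 1) / 2)  # 1-based radial bin
  ok <- k >= 1 & k <= nr
  ifelse(ok, k + j * nr, NA_integer_)   # 1-based combined bin index
}

# forward intersection parameter of ray P + t*u with the circle |x| = radius
ray_exit_t <- function(px, py, ux, uy, radius) {
  b <- px * ux + py * uy
  disc <- b^2 - (px^2 + py^2 - radius^2)
  disc[disc < 0] <- 0
  -b + sqrt(disc)
}
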