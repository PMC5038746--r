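# Pure-R scalar reference implementation of the transport loop. It consumes
# the same Lehmer deviate stream as the compiled engine and mirrors its
# arithmetic expression-for-expression, so for any seed the two produce
# identical tallies. It exists as an executable specification of the engine
# and is exercised against it in the test suite; it is far too slow for
# production photon counts.

run_mc_reference <- function(wavelength_um, beam, stack, grid = grid_spec(),
                             n_photons = 100, seed = 1, stream = 0,
                             roulette_threshold = 1e-4, roulette_m = 10) {
  lm <- layer_matrix(stack, wavelength_um)
  nlay <- nrow(lm)
  mu_a <- unname(lm[, "mu_a"]); mu_s <- unname(lm[, "mu_s"])
  gg <- unname(lm[, "g"]); nn <- unname(lm[, "n"])
  z_top <- unname(lm[, "z_top"]); z_bot <- unname(lm[, "z_bot"])
  n_above <- stack$ambient_n; n_below <- stack$ambient_n_below
  nr <- grid$nr; nz <- grid$nz; dr <- grid$Rs_cm; dz <- grid$Ds_cm
  focus_depth <- if (isTRUE(beam$converging)) beam$focus_depth_cm else 0
  beam_radius <- beam$spot_radius_cm
  beam_cx <- beam$center_offset[1]; beam_cy <- beam$center_offset[2]

  state <- mix_seed(seed, stream)
  rng <- function() {
    state <<- minstd_next(state)
    minstd_u(state)
  }
  fres <- function(n1, n2, cos_i) {
    if (n1 == n2) return(0)
    sin_i <- sqrt(1 - cos_i * cos_i)
    sin_t <- n1 / n2 * sin_i
    if (sin_t >= 1) return(1)
    cos_t <- sqrt(1 - sin_t * sin_t)
    rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
    rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
    0.5 * (rs * rs + rp * rp)
  }

  A <- matrix(0, nr, nz); F_ <- matrix(0, nr, nz)
  F_over <- numeric(nz); T_r <- numeric(nr)
  A_over <- 0; T_over <- 0
  specular <- 0; diffuse_refl <- 0; lost <- 0
  TWO_PI <- 6.283185307179586

  for (ip in seq_len(n_photons)) {
    u_r <- rng(); u_phi <- rng()
    rl <- beam_radius * sqrt(u_r)
    phl <- TWO_PI * u_phi
    rx <- rl * cos(phl); ry <- rl * sin(phl)
    x <- beam_cx + rx; y <- beam_cy + ry; z <- 0
    if (focus_depth != 0) {
      sgn <- if (focus_depth > 0) 1 else -1
      vx <- -rx * sgn; vy <- -ry * sgn; vz <- abs(focus_depth)
      nrm <- sqrt(vx * vx + vy * vy + vz * vz)
      ux <- vx / nrm; uy <- vy / nrm; uz <- vz / nrm
    } else {
      ux <- 0; uy <- 0; uz <- 1
    }
    rsp <- fres(n_above, nn[1], uz)
    w <- 1 - rsp
    specular <- specular + rsp
    scale <- n_above / nn[1]
    ux <- ux * scale; uy <- uy * scale
    uz <- sqrt(1 - (ux * ux + uy * uy))
    layer <- 1
    alive <- TRUE
    s_left <- 0

    while (alive) {
      mt <- mu_a[layer] + mu_s[layer]
      if (s_left <= 0) s_left <- -log(rng())
      step <- s_left / mt
      db <- if (uz > 0) (z_bot[layer] - z) / uz
            else if (uz < 0) (z_top[layer] - z) / uz
            else 1e30
      if (db < 0) db <- 0
      hit <- db < step
      travel <- if (hit) db else step
      z_new <- if (hit) (if (uz > 0) z_bot[layer] else z_top[layer])
               else z + uz * travel
      if (uz > 0) {
        j0 <- floor(z / dz - 0.5) + 1
        j1 <- floor(z_new / dz - 0.5)
        if (j0 < 0) j0 <- 0
        if (j1 > nz - 1) j1 <- nz - 1
        if (j1 >= j0) for (j in j0:j1) {
          zp <- (j + 0.5) * dz
          t <- (zp - z) / uz
          xx <- x + ux * t; yy <- y + uy * t
          rr <- sqrt(xx * xx + yy * yy)
          ir <- trunc(rr / dr)
          if (ir < nr) F_[ir + 1, j + 1] <- F_[ir + 1, j + 1] + w
          else F_over[j + 1] <- F_over[j + 1] + w
        }
      }
      x <- x + ux * travel; y <- y + uy * travel; z <- z_new

      if (hit) {
        s_left <- s_left - travel * mt
        down <- uz > 0
        n1 <- nn[layer]
        n2 <- if (down) {
          if (layer == nlay) n_below else nn[layer + 1]
        } else {
          if (layer == 1) n_above else nn[layer - 1]
        }
        ci <- abs(uz)
        rf <- fres(n1, n2, ci)
        u_b <- rng()
        if (u_b <= rf) {
          uz <- -uz
        } else {
          scale <- n1 / n2
          uxn <- ux * scale; uyn <- uy * scale
          st2 <- uxn * uxn + uyn * uyn
          uzn <- sqrt(if (st2 < 1) 1 - st2 else 0)
          if (down) {
            if (layer == nlay) {
              ir <- trunc(sqrt(x * x + y * y) / dr)
              if (ir < nr) T_r[ir + 1] <- T_r[ir + 1] + w
              else T_over <- T_over + w
              alive <- FALSE
            } else {
              ux <- uxn; uy <- uyn; uz <- uzn; layer <- layer + 1
            }
          } else {
            if (layer == 1) {
              diffuse_refl <- diffuse_refl + w
              alive <- FALSE
            } else {
              ux <- uxn; uy <- uyn; uz <- -uzn; layer <- layer - 1
            }
          }
        }
      } else {
        s_left <- 0
        dw <- w * mu_a[layer] / mt
        iz <- trunc(z / dz)
        ir <- trunc(sqrt(x * x + y * y) / dr)
        if (ir < nr && iz < nz) A[ir + 1, iz + 1] <- A[ir + 1, iz + 1] + dw
        else A_over <- A_over + dw
        w <- w - dw
        if (w <= 0) { alive <- FALSE; next } # fully captured
        g <- gg[layer]
        u1 <- rng(); u2 <- rng()
        if (g == 0) {
          cost <- 2 * u1 - 1
        } else {
          tmp <- (1 - g * g) / (1 - g + 2 * g * u1)
          cost <- (1 + g * g - tmp * tmp) / (2 * g)
        }
        if (cost > 1) cost <- 1
        if (cost < -1) cost <- -1
        sint <- sqrt(1 - cost * cost)
        phi <- TWO_PI * u2
        cosp <- cos(phi); sinp <- sin(phi)
        if (abs(uz) > 0.99999) {
          ux <- sint * cosp
          uy <- sint * sinp
          uz <- cost * (if (uz >= 0) 1 else -1)
        } else {
          den <- sqrt(1 - uz * uz)
          uxn <- sint * (ux * uz * cosp - uy * sinp) / den + ux * cost
          uyn <- sint * (uy * uz * cosp + ux * sinp) / den + uy * cost
          uzn <- -den * sint * cosp + uz * cost
          ux <- uxn; uy <- uyn; uz <- uzn
        }
        if (w < roulette_threshold) {
          u3 <- rng()
          if (u3 < 1 / roulette_m) w <- w * roulette_m
          else { w <- 0; alive <- FALSE }
        }
      }
    }
  }

  raw <- list(absorbed = A, flux = F_, flux_overflow = F_over,
              transmit_r = T_r, transmit_overflow = T_over,
              absorbed_overflow = A_over, specular = specular,
              diffuse_reflectance = diffuse_refl, lost = lost,
              launched = n_photons)
  finish_grid(raw, beam, grid, wavelength_um, n_photons, seed, stream)
}
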