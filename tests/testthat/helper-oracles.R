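# Independent oracles, written against the formulas directly (plain R
# double loops) -- never against the package's compiled energy path.

# full energy breakdown by brute-force double loop
brute_energy <- function(state, arr, eps, params) {
  pos <- state$positions; ori <- state$orientations
  seq_ <- state$sequence
  n <- nrow(pos)
  iso <- 0; dir <- 0; bond <- 0; viol <- FALSE
  np <- nrow(arr$patch_axes)
  rot <- function(i, v) as.numeric(quat_rotate(ori[i, ], v))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    r <- sqrt(sum((pos[j, ] - pos[i, ])^2))
    if (j != i + 1) {
      if (r < params$hardcore_contact) viol <- TRUE
      else if (r <= params$r_max)
        iso <- iso + eps[seq_[i], seq_[j]] *
          (1 - 1 / (1 + exp(2.5 * (params$r_max - r))))
    }
    if (np > 0) {
      for (a in seq_len(np)) for (b in seq_len(np)) {
        wa <- rot(i, arr$patch_axes[a, ])
        wb <- rot(j, arr$patch_axes[b, ])
        pa <- pos[i, ] + params$bead_radius * wa
        pb <- pos[j, ] + params$bead_radius * wb
        d <- pb - pa
        R <- sqrt(sum(d^2))
        if (R >= params$r_cut) next
        u <- d / R
        x <- params$sigma / R
        dir <- dir + params$s * params$eps_p *
          (sum(wa * u) * sum(wb * u))^params$nu * (5 * x^12 - 6 * x^10)
      }
    }
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (params$chain_model == "FRC") {
        d <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
      } else {
        pf <- pos[i, ] + params$bead_radius * rot(i, arr$anchor_axes[1, ])
        pb <- pos[i + 1, ] +
          params$bead_radius * rot(i + 1, arr$anchor_axes[2, ])
        d <- sqrt(sum((pf - pb)^2))
      }
      bond <- bond + 0.5 * params$spring_k * (d - params$spring_rest)^2
    }
  }
  list(isotropic = iso, directional = dir, bond = bond,
       total = if (viol) Inf else iso + dir + bond,
       hardcore_violated = viol)
}

# a random valid chain with random orientations and sequence
random_valid_chain <- function(n, q, seed, params = model_params()) {
  initial_chain(n, q, "random_walk", seed = seed, params = params)
}

# quadrature CDF of the 2-bead bonded Boltzmann law p(x) ~ x^2 exp(-k(x-d0)^2 / 2T)
bond_length_cdf <- function(x, temperature, params = model_params()) {
  k <- params$spring_k; d0 <- params$spring_rest
  grid <- seq(1e-4, d0 + 10 * sqrt(temperature / k), length.out = 20001)
  dens <- grid^2 * exp(-0.5 * k * (grid - d0)^2 / temperature)
  cum <- cumsum(dens); cum <- cum / cum[length(cum)]
  approx(grid, cum, xout = x, yleft = 0, yright = 1)$y
}

# two-bead facing-patch state with centers d apart along x
facing_pair <- function(d) {
  chain_state(rbind(c(0, 0, 0), c(d, 0, 0)),
              rbind(quat_from_axis_angle(c(0, 1, 0), pi / 2),
                    quat_from_axis_angle(c(0, 1, 0), -pi / 2)))
}

# exhaustive DESIGN oracle on a frozen toy conformation: all q^n
# sequences, entropy-constrained minimum isotropic energy
exhaustive_design <- function(target, arr, eps, params, q,
                              heterogeneity = 0.8) {
  n <- nrow(target$positions)
  seqs <- as.matrix(expand.grid(rep(list(1:q), n)))
  entropy <- apply(seqs, 1, function(s) {
    p <- table(s) / length(s); -sum(p * log(p))
  })
  e <- apply(seqs, 1, function(s) {
    st <- target; st$sequence <- as.integer(s)
    brute_energy(st, arr, eps, params)$total
  })
  ok <- entropy >= heterogeneity * log(q) - 1e-12
  best <- min(e[ok])
  list(energies = e, entropy = entropy,
       optimum = seqs[ok & abs(e - best) < 1e-9, , drop = FALSE],
       best_energy = best)
}
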