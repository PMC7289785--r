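# Shared fixtures: published parameter values and small simulation helpers.

gh_truth <- function(sigma2 = 0.0247) {
  list(theta = list(baseline = 0.056, width = 0.184, amplitude = 1.69,
                    kel = 3.6, ke0 = 1.25, iemax = 0.648, ec50 = 0.609),
       omega2 = c(baseline = 0.0288, width = 0.0434, kel = 0.225,
                  amplitude = 3.46, bov_width = 0.104, bov_kel = 0.00775),
       sigma2 = sigma2)
}

prl_truth <- function() {
  list(theta = list(kr = 0.011, kel = 1.25, ks = 13.3, amp24 = 0.168,
                    phase24 = 17.3, amp12 = 0.095, phase12 = 10.2,
                    iemax = 0.91, ec50 = 1.27, slope = 2.73),
       omega2 = c(ks = 0.068, amp24 = 0.57, amp12 = 0.87),
       sigma2 = 0.049)
}

# pulse locations actually used by the generator, in the long format the
# GH fit consumes
truth_pulses <- function(tab) {
  tr <- attr(tab, "truth")
  out <- list()
  for (id in seq_along(tr)) {
    if (is.null(tr[[id]]$gh_occ)) next
    occs <- sort(unique(tab$OCC[tab$ID == id & tab$DVID == 2 &
                                  tab$EVID == 0]))
    for (k in seq_along(tr[[id]]$gh_occ)) {
      pl <- tr[[id]]$gh_occ[[k]]$pulses
      if (!nrow(pl)) next
      out[[length(out) + 1]] <- data.frame(
        ID = id, OCC = occs[k], PULSE_TIME_H = pl$location,
        MASS = NA_real_, WIDTH = NA_real_, AUGMENTED = 0)
    }
  }
  do.call(rbind, out)
}

# one synthetic placebo GH profile at the published parameters
gh_profile_fixture <- function(noise_cv = 0.15, params = gh_params()) {
  eta <- rnorm(3, 0, sqrt(params$omega2[c("baseline", "width", "kel")]))
  p_i <- params
  p_i$baseline <- params$baseline * exp(eta[1])
  p_i$width <- params$width * exp(eta[2])
  p_i$kel <- params$kel * exp(eta[3])
  st <- seq(0, 12, 1 / 3)
  pt <- generate_pulse_times(14, start = -2)
  mass <- params$amplitude *
    exp(rnorm(length(pt), 0, sqrt(params$omega2["amplitude"])))
  pred <- gh_concentration(p_i, data.frame(location = pt, mass = mass), st)
  y <- lloq_substitute(pred * (1 + rnorm(length(st), 0, noise_cv)))$value
  list(times = st, y = y, pulses = pt, mass = mass, params = p_i)
}

# greedy 1-1 matching of estimated to true pulse locations
match_pulses <- function(est, true_loc, true_mass, tol = 1 / 3) {
  matched <- rep(FALSE, length(true_loc))
  used <- rep(FALSE, length(est))
  for (j in order(-true_mass)) {
    d <- abs(est - true_loc[j])
    d[used] <- Inf
    if (length(d) && min(d) <= tol + 1e-9) {
      used[which.min(d)] <- TRUE
      matched[j] <- TRUE
    }
  }
  list(matched = matched, used = used)
}

# closed-form linear two-compartment concentration via the matrix exponential
pk_linear_oracle <- function(cfg, dose_mg, times) {
  A <- rbind(c(-cfg$ka, 0, 0),
             c(cfg$ka, -(cfg$cl + cfg$q) / cfg$vc, cfg$q / cfg$vp),
             c(0, cfg$q / cfg$vc, -cfg$q / cfg$vp))
  e <- eigen(A)
  x0 <- c(dose_mg * 1000, 0, 0)
  vapply(times, function(tt) {
    Re((e$vectors %*% diag(exp(e$values * tt)) %*%
          solve(e$vectors, x0))[2]) / cfg$vc
  }, 0)
}
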