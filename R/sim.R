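#' Define a stochastic replication program
#'
#' A replication program places origins on the bin grid and gives each an
#' overall firing competence `p` (probability the origin fires at all in a
#' given cell) and a mean firing time `tau`.  In each simulated cell a
#' competent origin fires at an exponentially distributed time with mean
#' `tau` (or exactly at `tau` under `time_model = "fixed"`, useful for
#' deterministic checks); forks then move outward at a constant speed.  An
#' origin overrun by an incoming fork before its own firing time is
#' passively replicated and contributes no forks — this is what makes
#' realized origin efficiencies smaller than `p`.
#'
#' @param layout a [genome_layout()].
#' @param origins data.frame with columns `position_bin` (1-based bin
#'   index), `p` in `[0, 1]`, `tau >= 0` (arbitrary time units), and
#'   optionally `chrom` (defaults to the first chromosome).  Positions must
#'   be strictly increasing within each chromosome.
#' @param fork_speed fork speed in bins per time unit (> 0, shared by all
#'   forks).
#' @param time_model `"exponential"` (default) or `"fixed"` (zero-variance
#'   firing times).
#' @return a `replication_program`.
#' @export
replication_program <- function(layout, origins, fork_speed = 150,
                                time_model = c("exponential", "fixed")) {
  time_model <- match.arg(time_model)
  if (!is.data.frame(origins) || !all(c("position_bin", "p", "tau") %in% names(origins)))
    stop("origins must be a data.frame with position_bin, p, tau")
  if (is.null(origins$chrom)) origins$chrom <- layout$chrom$name[1]
  ci <- match(origins$chrom, layout$chrom$name)
  if (anyNA(ci)) stop("unknown chromosome in origins")
  if (any(origins$position_bin < 1 | origins$position_bin > layout$chrom$n_bins[ci]))
    stop("origin bin outside chromosome")
  if (any(origins$p < 0 | origins$p > 1)) stop("firing probability p must be in [0, 1]")
  if (any(origins$tau < 0)) stop("mean firing time tau must be >= 0")
  if (fork_speed <= 0) stop("fork_speed must be > 0")
  origins <- origins[order(ci, origins$position_bin), , drop = FALSE]
  for (cc in unique(origins$chrom)) {
    pos <- origins$position_bin[origins$chrom == cc]
    if (anyDuplicated(pos)) stop("origin bins must be strictly increasing on ", cc)
  }
  rownames(origins) <- NULL
  structure(
    list(layout = layout,
         origins = origins[, c("chrom", "position_bin", "p", "tau")],
         fork_speed = fork_speed, time_model = time_model),
    class = "replication_program"
  )
}

#' @export
print.replication_program <- function(x, ...) {
  cat(sprintf("<replication_program> %d origin(s), fork speed %g bins/unit, %s firing times\n",
              nrow(x$origins), x$fork_speed, x$time_model))
  print(x$origins, row.names = FALSE)
  invisible(x)
}

# Draw per-cell firing times for one chromosome's origins.
# Stream order (fixed so tests can replay it): first the n_cells x J fired
# indicators, then the n_cells x J times.  Unfired origins get time Inf.
draw_firing_times <- function(p, tau, n_cells, time_model) {
  J <- length(p)
  fired <- matrix(stats::runif(n_cells * J), n_cells, J) <
    matrix(p, n_cells, J, byrow = TRUE)
  t <- if (time_model == "exponential") {
    matrix(stats::rexp(n_cells * J), n_cells, J) *
      matrix(tau, n_cells, J, byrow = TRUE)
  } else {
    matrix(tau, n_cells, J, byrow = TRUE)
  }
  t[!fired] <- Inf
  t
}

#' Simulate a population of replicating cells
#'
#' Simulates `n_cells` independent cells executing the replication program.
#' In each cell, each bin is replicated by whichever fork (or in-place
#' origin firing) reaches it first; when two converging forks reach a bin at
#' exactly the same time the leftward-moving fork wins, except at the bin of
#' an origin that itself fired, which counts half to each direction.  A bin
#' belonging to a cell in which no origin fired is left unreplicated and
#' excluded from that bin's denominator (vanishingly rare under realistic
#' programs).
#'
#' @param program a [replication_program()].
#' @param n_cells number of simulated cells (>= 1).
#' @param seed RNG seed.
#' @return a `fork_direction_profile`: `layout`; `f_right` — per-bin
#'   fraction of cells whose replicating fork moved rightward; `origins` —
#'   the program's origin table with a `realized_efficiency` column, the
#'   fraction of cells in which the origin fired actively (never exceeds
#'   `p`: passive replication only removes firings).
#' @export
simulate_population <- function(program, n_cells, seed) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  ori_all <- program$origins
  if (all(ori_all$p <= 0)) stop("unreplicable genome: no origin can ever fire")
  layout <- program$layout
  set.seed(as.integer(seed))
  f_right <- numeric(layout$n_bins)
  realized <- numeric(nrow(ori_all))
  slices <- chrom_slices(layout)
  for (k in seq_len(nrow(layout$chrom))) {
    cname <- layout$chrom$name[k]
    oi <- which(ori_all$chrom == cname)
    if (length(oi) == 0 || all(ori_all$p[oi] <= 0))
      stop("unreplicable genome: no origin can ever fire on ", cname)
    res <- simulate_chromosome(
      o = ori_all$position_bin[oi], p = ori_all$p[oi], tau = ori_all$tau[oi],
      n_bins = layout$chrom$n_bins[k], v = program$fork_speed,
      n_cells = n_cells, time_model = program$time_model)
    f_right[slices[[k]]] <- res$f_right
    realized[oi] <- res$realized
  }
  ori_all$realized_efficiency <- realized
  structure(list(layout = layout, f_right = f_right, origins = ori_all),
            class = "fork_direction_profile")
}

# Core single-chromosome engine.  Replication time of bin x in a cell is
# min_j (t_j + |x - o_j| / v); the winning origin determines fork direction.
# Passive replication needs no special casing for bin times (a passively
# replicated origin is never the minimiser for any bin), only for realized
# efficiency.  Vectorised over cells via running minima of t_j -/+ o_j/v,
# with winner indices carried along: the same origin winning a bin from
# both directions is only possible at distance 0, which identifies in-place
# firing without comparing floating-point times for equality.
simulate_chromosome <- function(o, p, tau, n_bins, v, n_cells, time_model) {
  J <- length(o)
  t <- draw_firing_times(p, tau, n_cells, time_model)
  om <- matrix(o / v, n_cells, J, byrow = TRUE)
  a <- t - om  # right-moving forks: arrival(x) = x/v + min_{o_j <= x} a_j
  b <- t + om  # left-moving forks:  arrival(x) = -x/v + min_{o_j >= x} b_j
  Rm <- a                                  # running min, left to right
  Ri <- matrix(1L, n_cells, J)             # index of the minimiser
  if (J > 1) for (j in 2:J) {
    upd <- a[, j] < Rm[, j - 1]            # ties keep the leftmost origin
    Rm[, j] <- ifelse(upd, a[, j], Rm[, j - 1])
    Ri[, j] <- ifelse(upd, j, Ri[, j - 1])
  }
  Lm <- b                                  # running min, right to left
  Li <- matrix(as.integer(J), n_cells, J)
  if (J > 1) for (j in (J - 1):1) {
    upd <- b[, j] < Lm[, j + 1]            # ties keep the rightmost origin
    Lm[, j] <- ifelse(upd, b[, j], Lm[, j + 1])
    Li[, j] <- ifelse(upd, j, Li[, j + 1])
  }
  kR <- findInterval(seq_len(n_bins), o)          # last origin <= x (0 if none)
  kL <- findInterval(seq_len(n_bins) - 0.5, o) + 1  # first origin >= x (J+1 if none)

  f_right <- numeric(n_bins)
  inf <- rep(Inf, n_cells)
  for (x in seq_len(n_bins)) {
    has_r <- kR[x] >= 1
    has_l <- kL[x] <= J
    tR <- if (has_r) x / v + Rm[, kR[x]] else inf
    tL <- if (has_l) -x / v + Lm[, kL[x]] else inf
    replicated <- is.finite(tR) | is.finite(tL)
    n_rep <- sum(replicated)
    if (n_rep == 0)
      stop("bin ", x, " was never replicated in any simulated cell")
    # same winner from both directions <=> the origin at this bin fired and
    # won in place: half a fork to each direction
    in_place <- if (has_r && has_l)
      replicated & Ri[, kR[x]] == Li[, kL[x]] else rep(FALSE, n_cells)
    right <- !in_place & tR < tL           # remaining exact ties: left wins
    f_right[x] <- (sum(right) + 0.5 * sum(in_place)) / n_rep
  }

  realized <- numeric(J)
  for (j in seq_len(J)) {
    arr_other <- rep(Inf, n_cells)
    for (i in seq_len(J)) {
      if (i == j) next
      arr_other <- pmin(arr_other, t[, i] + abs(o[j] - o[i]) / v)
    }
    realized[j] <- mean(is.finite(t[, j]) & t[, j] < arr_other)
  }
  list(f_right = f_right, realized = realized)
}

#' @export
print.fork_direction_profile <- function(x, ...) {
  cat(sprintf("<fork_direction_profile> %d bins, %d origin(s)\n",
              x$layout$n_bins, nrow(x$origins)))
  print(x$origins, row.names = FALSE)
  invisible(x)
}

#' Expected (noise-free) polymerase track from fork directionality
#'
#' Pol epsilon synthesises the leading strand: where forks move rightward
#' its nascent-strand rNMPs map to the top strand, so
#' `PT_epsilon = 2 * f_right - 1`.  Pol delta and Pol alpha are
#' lagging-strand polymerases with the opposite sign,
#' `PT_delta = PT_alpha = 1 - 2 * f_right`.
#'
#' @param f_right per-bin rightward-fork fractions (a numeric vector, or a
#'   `fork_direction_profile` whose `f_right` is used).
#' @param polymerase one of `"delta"`, `"epsilon"`, `"alpha"`.
#' @return per-bin expected PT values in `[-1, 1]`.
#' @export
expected_track <- function(f_right, polymerase) {
  polymerase <- check_polymerase(polymerase)
  if (inherits(f_right, "fork_direction_profile")) f_right <- f_right$f_right
  if (any(f_right < 0 | f_right > 1)) stop("f_right must lie in [0, 1]")
  if (polymerase == "epsilon") 2 * f_right - 1 else 1 - 2 * f_right
}

#' Define a count-noise model
#'
#' @param mean_depth expected rNMPs per bin per strand-pair (lambda > 0).
#' @param background_fraction portion `b` in `[0, 1)` of the signal spread
#'   uniformly over both strands, emulating residual ribonucleotide excision
#'   repair and mapping noise.
#' @return a `noise_model`.
#' @export
noise_model <- function(mean_depth = 50, background_fraction = 0.05) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  structure(list(mean_depth = mean_depth,
                 background_fraction = background_fraction),
            class = "noise_model")
}

#' Sample Pu-Seq-like strand counts from a fork-direction profile
#'
#' Per bin, the top-strand signal fraction is `s = f_right` for Pol epsilon
#' and `s = 1 - f_right` for Pol delta / Pol alpha; expected counts are
#' `lambda * ((1 - b) * s + b / 2)` on the top strand and the complement on
#' the bottom strand, drawn independently Poisson.  Replicate `r` uses RNG
#' seed `seed + r` so replicates are reproducible individually.
#'
#' @param profile a `fork_direction_profile` (or a bare `f_right` vector
#'   plus `layout`).
#' @param polymerase one of `"delta"`, `"epsilon"`, `"alpha"`.
#' @param noise a [noise_model()].
#' @param replicate replicate number (integer >= 1).
#' @param seed base RNG seed.
#' @param layout required if `profile` is a bare numeric vector.
#' @param strain strain label for the resulting counts object.
#' @return a `binned_strand_counts`.
#' @export
sample_counts <- function(profile, polymerase, noise = noise_model(),
                          replicate = 1L, seed = 1L, layout = NULL,
                          strain = "sim") {
  polymerase <- check_polymerase(polymerase)
  if (inherits(profile, "fork_direction_profile")) {
    layout <- profile$layout
    f_right <- profile$f_right
  } else {
    if (is.null(layout)) stop("layout is required with a bare f_right vector")
    f_right <- profile
  }
  s <- if (polymerase == "epsilon") f_right else 1 - f_right
  b <- noise$background_fraction
  lam_top <- noise$mean_depth * ((1 - b) * s + b / 2)
  lam_bot <- noise$mean_depth * ((1 - b) * (1 - s) + b / 2)
  set.seed(as.integer(seed) + as.integer(replicate))
  top <- stats::rpois(length(lam_top), lam_top)
  bottom <- stats::rpois(length(lam_bot), lam_bot)
  binned_strand_counts(layout, strain, polymerase, replicate, top, bottom)
}

#' Simulate a complete Pu-Seq experiment
#'
#' Runs [simulate_population()] once and samples strand-count tables for all
#' three polymerase datasets (Pol delta, Pol epsilon, Pol alpha) with the
#' requested number of biological replicates.  Count sampling for polymerase
#' `q` (1 = delta, 2 = epsilon, 3 = alpha), replicate `r`, uses seed
#' `seed + 10 * q + r`, so every table has its own reproducible stream.
#'
#' @param program a [replication_program()].
#' @param noise a [noise_model()].
#' @param n_cells cells in the simulated population.
#' @param replicates biological replicates per polymerase.
#' @param seed base RNG seed.
#' @param strain strain label.
#' @return list with `truth` (the `fork_direction_profile`) and `counts`
#'   (flat list of `binned_strand_counts`, all polymerase x replicate
#'   combinations).
#' @export
simulate_puseq <- function(program, noise = noise_model(), n_cells = 10000,
                           replicates = 2, seed = 1L, strain = "WT") {
  truth <- simulate_population(program, n_cells, seed)
  counts <- list()
  for (q in seq_along(POLYMERASES)) {
    for (r in seq_len(replicates)) {
      counts[[length(counts) + 1]] <- sample_counts(
        truth, POLYMERASES[q], noise,
        replicate = r, seed = as.integer(seed) + 10L * q, strain = strain)
    }
  }
  list(truth = truth, counts = counts)
}

#' Example replication program
#'
#' A single 900 kb chromosome (3,000 bins of 300 bp) carrying 10 origins at
#' 300-bin spacing whose firing competences span 0.25-1.0 in a scrambled
#' spatial order, all with mean firing time 1 time unit and fork speed 150
#' bins per time unit.  Under this program neighbouring origins compete
#' mildly (passive replication shaves a few percent off each competence), so
#' realized efficiencies span roughly 0.2-1.0 — a convenient test bed for
#' the origin-calling pipeline.
#'
#' @param bin_width bin width in bp.
#' @return a [replication_program()].
#' @export
example_program <- function(bin_width = 300) {
  layout <- genome_layout(c(chrI = 3000 * bin_width), bin_width = bin_width)
  origins <- data.frame(
    position_bin = seq(150, 2850, by = 300),
    p   = c(0.50, 1.00, 0.33, 0.75, 0.25, 0.92, 0.58, 0.83, 0.42, 0.67),
    tau = 1
  )
  replication_program(layout, origins, fork_speed = 150)
}
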