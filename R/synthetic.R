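#' Synthetic fluorescence trace generator configuration
#'
#' Parameters of the seeded trace generator: a slowly bleaching baseline
#' carrying Poisson-arriving calcium transients (linear rise, exponential
#' decay) plus additive Gaussian noise. Defaults emulate a 3-minute
#' baseline imaging trial: 1 transient per minute, amplitudes 0.8-1.2
#' delta-F/F, 0.5 s rise, 5 s decay constant (so the weakest event stays
#' above the 0.5 delta-F/F criterion for about 2.5 s, comfortably past the
#' 2 s width criterion), noise sd 0.05 delta-F/F at 5 Hz.
#'
#' @param n_cells Number of traces.
#' @param duration_s Trace duration (s).
#' @param fs Sampling rate (Hz).
#' @param event_rate Transients per minute (Poisson arrivals).
#' @param amp_range Length-2 delta-F/F amplitude range (uniform).
#' @param decay_tau_s Exponential decay constant (s).
#' @param rise_s Linear rise time (s).
#' @param noise_sd Additive Gaussian noise sd, delta-F/F units.
#' @param bleach_slope Fractional baseline decay per minute (exponential).
#' @param f0_level Baseline fluorescence (a.u.).
#' @param min_separation_s Refractory gap between consecutive onsets (s).
#'   Arrivals are a hard-core renewal process -- exponential gaps shifted by
#'   this refractory period, rate-corrected so the mean rate stays exactly
#'   `event_rate` -- so injected events never fuse and per-event ground
#'   truth (onset, width) stays well defined. Must satisfy
#'   `min_separation_s < 60 / event_rate`.
#' @param seed Integer seed.
#' @return An object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(n_cells = 100, duration_s = 180, fs = 5,
                             event_rate = 1, amp_range = c(0.8, 1.2),
                             decay_tau_s = 5, rise_s = 0.5, noise_sd = 0.05,
                             bleach_slope = 0, f0_level = 100,
                             min_separation_s = 10, seed = 1L) {
  if (n_cells < 1 || duration_s <= 0 || fs <= 0)
    stop("trace_gen_config: 'n_cells', 'duration_s' and 'fs' must be positive")
  if (event_rate < 0 || noise_sd < 0 || bleach_slope < 0 || f0_level <= 0)
    stop("trace_gen_config: rates, noise, bleach and baseline must be valid")
  if (length(amp_range) != 2L || amp_range[1] > amp_range[2] || amp_range[1] <= 0)
    stop("trace_gen_config: 'amp_range' must be a positive min-max pair")
  if (decay_tau_s <= 0 || rise_s <= 0)
    stop("trace_gen_config: kernel times must be > 0")
  if (min_separation_s < 0 ||
      (event_rate > 0 && min_separation_s >= 60 / event_rate))
    stop("trace_gen_config: 'min_separation_s' must be < 60 / event_rate")
  structure(list(n_cells = n_cells, duration_s = duration_s, fs = fs,
                 event_rate = event_rate, amp_range = amp_range,
                 decay_tau_s = decay_tau_s, rise_s = rise_s,
                 noise_sd = noise_sd, bleach_slope = bleach_slope,
                 f0_level = f0_level,
                 min_separation_s = min_separation_s,
                 seed = as.integer(seed)),
            class = "trace_gen_config")
}

#' Nominal above-threshold width of a transient kernel
#'
#' Analytic duration for which the rise-and-decay kernel of amplitude
#' `amplitude` exceeds `threshold`: from the rise crossing
#' `rise_s * threshold / amplitude` to the decay crossing
#' `rise_s + decay_tau_s * log(amplitude / threshold)`. Zero when the
#' amplitude never reaches the threshold.
#'
#' @param amplitude Peak delta-F/F of the event.
#' @param rise_s,decay_tau_s Kernel rise time and decay constant (s).
#' @param threshold Detection threshold (delta-F/F).
#' @return Width in seconds.
#' @export
nominal_event_width <- function(amplitude, rise_s = 0.5, decay_tau_s = 5,
                                threshold = 0.5) {
  ifelse(amplitude <= threshold, 0,
         rise_s + decay_tau_s * log(amplitude / threshold) -
           rise_s * threshold / amplitude)
}

#' Generate synthetic per-cell fluorescence traces with ground truth
#'
#' Each cell's fluorescence is
#' `F(t) = F0(t) * (1 + sum of event kernels) + noise`, where `F0` decays
#' exponentially at `bleach_slope` per minute, events arrive as a
#' refractory (hard-core) renewal process with mean rate `event_rate` per
#' minute and uniform amplitudes, and each kernel rises linearly over
#' `rise_s` then decays with constant `decay_tau_s`. Fully reproducible
#' from the config seed; the caller's RNG state is untouched.
#'
#' @param cfg A [trace_gen_config()].
#' @return A list with `traces` (list of [fluor_trace()]) and
#'   `ground_truth` (data frame `cell_id`, `onset_s`, `amplitude`,
#'   `width_s` with the analytic above-0.5 width).
#' @export
gen_traces <- function(cfg) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  rng <- .seeded_rng(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1L) / cfg$fs
  f0 <- cfg$f0_level * exp(-cfg$bleach_slope * tt / 60)

  # shifted-exponential inter-event gaps with mean 60 / event_rate
  draw_onsets <- function() {
    if (cfg$event_rate <= 0) return(numeric(0))
    mean_gap <- 60 / cfg$event_rate
    exp_rate <- 1 / (mean_gap - cfg$min_separation_s)
    onsets <- numeric(0)
    t_next <- -log(rng$unif(1)) / exp_rate  # first arrival: plain exponential
    while (t_next < cfg$duration_s) {
      onsets <- c(onsets, t_next)
      t_next <- t_next + cfg$min_separation_s - log(rng$unif(1)) / exp_rate
    }
    onsets
  }

  traces <- vector("list", cfg$n_cells)
  gt <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    onsets <- draw_onsets()
    n_ev <- length(onsets)
    amps <- rng$unif(n_ev, cfg$amp_range[1], cfg$amp_range[2])
    s <- numeric(n)
    for (k in seq_len(n_ev)) {
      dt <- tt - onsets[k]
      kern <- ifelse(dt < 0, 0,
                     ifelse(dt <= cfg$rise_s, dt / cfg$rise_s,
                            exp(-(dt - cfg$rise_s) / cfg$decay_tau_s)))
      s <- s + amps[k] * kern
    }
    noise <- if (cfg$noise_sd > 0) rng$norm(n, sd = cfg$noise_sd) * f0 else 0
    values <- pmax(0, f0 * (1 + s) + noise)
    traces[[i]] <- fluor_trace(values, fs = cfg$fs, cell_id = i)
    gt[[i]] <- if (n_ev > 0)
      data.frame(cell_id = i, onset_s = onsets, amplitude = amps,
                 width_s = nominal_event_width(amps, cfg$rise_s,
                                               cfg$decay_tau_s))
    else NULL
  }
  keep <- gt[!vapply(gt, is.null, logical(1))]
  empty <- data.frame(cell_id = integer(0), onset_s = numeric(0),
                      amplitude = numeric(0), width_s = numeric(0))
  list(traces = traces,
       ground_truth = if (length(keep)) do.call(rbind, keep) else empty)
}

#' Generate a labelled shape mask with known geometry
#'
#' Places non-overlapping circles, ellipses or irregular blobs into an
#' integer label mask by rejection sampling. Analytic area and perimeter are
#' reported where closed forms exist (circle exactly; ellipse via the
#' Ramanujan II approximation, accurate to < 1e-6 relative for the aspect
#' ratios generated; blobs carry `NA`).
#'
#' @param n_shapes Number of shapes (0 gives an all-zero mask).
#' @param shape_kind `"circle"`, `"ellipse"` or `"blob"`.
#' @param size_range Length-2 radius range in px.
#' @param image_size Length-2 `c(rows, cols)` of the mask.
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up.
#' @return A list with `mask` (integer matrix, labels `1..n_shapes`) and
#'   `truth` (data frame `cell_id`, `area`, `perimeter`).
#' @export
gen_label_mask <- function(n_shapes, shape_kind = c("circle", "ellipse", "blob"),
                           size_range = c(8, 20), image_size = c(256, 256),
                           seed = 1L, max_tries = 200L * max(1L, n_shapes)) {
  shape_kind <- match.arg(shape_kind)
  mask <- matrix(0L, image_size[1], image_size[2])
  truth <- data.frame(cell_id = integer(0), area = numeric(0),
                      perimeter = numeric(0))
  if (n_shapes == 0) return(list(mask = mask, truth = truth))
  rng <- .seeded_rng(seed)

  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  placed <- 0L
  tries <- 0L
  specs <- vector("list", n_shapes)
  while (placed < n_shapes) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("gen_label_mask: could not place ", n_shapes,
           " non-overlapping shapes in ", max_tries, " tries")
    r <- rng$unif(1, size_range[1], size_range[2])
    elong <- if (shape_kind == "ellipse") rng$unif(1, 1.2, 2.5) else 1
    theta <- rng$unif(1, 0, pi)
    r_bound <- switch(shape_kind, circle = r, ellipse = r, blob = 1.35 * r)
    cx <- rng$unif(1, r_bound + 2, image_size[2] - r_bound - 2)
    cy <- rng$unif(1, r_bound + 2, image_size[1] - r_bound - 2)
    if (placed > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      if (any(d < radii + r_bound + 2)) next
    }
    placed <- placed + 1L
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r_bound)
    specs[[placed]] <- list(cy = cy, cx = cx, r = r, elong = elong,
                            theta = theta,
                            ph = rng$unif(2, 0, 2 * pi))
  }

  yy <- matrix(seq_len(image_size[1]), image_size[1], image_size[2])
  xx <- matrix(seq_len(image_size[2]), image_size[1], image_size[2],
               byrow = TRUE)
  for (i in seq_len(n_shapes)) {
    sp <- specs[[i]]
    dy <- yy - sp$cy
    dx <- xx - sp$cx
    if (shape_kind == "circle") {
      inside <- dy^2 + dx^2 <= sp$r^2
      area <- pi * sp$r^2
      perim <- 2 * pi * sp$r
    } else if (shape_kind == "ellipse") {
      a <- sp$r
      b <- sp$r / sp$elong
      u <- dx * cos(sp$theta) + dy * sin(sp$theta)
      v <- -dx * sin(sp$theta) + dy * cos(sp$theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      area <- pi * a * b
      h <- ((a - b) / (a + b))^2
      perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    } else {
      phi <- atan2(dy, dx)
      rad <- sp$r * (1 + 0.2 * sin(3 * phi + sp$ph[1]) +
                       0.1 * sin(5 * phi + sp$ph[2]))
      inside <- dy^2 + dx^2 <= rad^2
      area <- NA_real_
      perim <- NA_real_
    }
    mask[inside] <- i
    truth <- rbind(truth, data.frame(cell_id = i, area = area,
                                     perimeter = perim))
  }
  list(mask = mask, truth = truth)
}

#' Paint traces into a synthetic image stack
#'
#' Frame `t` takes the value of each cell's trace over its labelled region,
#' on a constant background, plus optional Gaussian pixel noise. With zero
#' noise, [extract_traces()] recovers the input traces exactly.
#'
#' @param traces List of [fluor_trace()], one per mask label (matched by
#'   `cell_id`).
#' @param mask Integer label matrix.
#' @param background Background intensity (a.u.).
#' @param noise_sd Gaussian pixel noise sd (a.u.).
#' @param seed Integer seed for the noise stream.
#' @return A numeric array `(rows, cols, frames)`.
#' @export
gen_movie <- function(traces, mask, background = 10, noise_sd = 0, seed = 1L) {
  labs <- sort(unique(as.integer(mask[mask > 0])))
  ids <- vapply(traces, function(tr) as.integer(tr$cell_id), integer(1))
  if (!setequal(labs, ids) || length(labs) != length(traces))
    stop("gen_movie: mask labels and trace cell ids must match one-to-one")
  nt <- if (length(traces)) length(traces[[1L]]$values) else
    stop("gen_movie: need at least one trace")
  if (any(vapply(traces, function(tr) length(tr$values), integer(1)) != nt))
    stop("gen_movie: traces must share one length")

  stack <- array(background, dim = c(nrow(mask), ncol(mask), nt))
  idx_by_lab <- lapply(labs, function(l) which(mask == l))
  npx <- nrow(mask) * ncol(mask)
  for (t in seq_len(nt)) {
    off <- (t - 1L) * npx
    for (j in seq_along(labs)) {
      tr <- traces[[match(labs[j], ids)]]
      stack[off + idx_by_lab[[j]]] <- tr$values[t]
    }
  }
  if (noise_sd > 0) {
    rng <- .seeded_rng(seed)
    stack <- stack + array(rng$norm(length(stack), sd = noise_sd), dim = dim(stack))
  }
  stack
}
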