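# Trace plumbing: filtering, averaging, tabular trace files and the
# synthetic-fixture generator shared by the tests and the BSS pipeline.

#' @importFrom signal butter filtfilt filter
NULL

#' Band-pass filter an LFP trace
#'
#' Zero-phase (forward-backward) Butterworth filtering, the standard
#' treatment for evoked potentials: a 100 Hz high-pass stabilises the
#' baseline of recorded traces and a 2 kHz low-pass removes fast noise,
#' without shifting peak latencies. `highpass = 0` gives a pure low-pass.
#'
#' @param trace an [LfpTrace-class].
#' @param spec a [FilterSpec-class].
#' @return the filtered [LfpTrace-class].
#' @examples
#' tr <- lfpTrace(sin(2 * pi * 500 * seq(0, 0.2, 2.5e-5)), dt = 0.025)
#' out <- filterTrace(tr, filterSpec(100, 2000))
#' @export
filterTrace <- function(trace, spec = filterSpec()) {
  stopifnot(is(trace, "LfpTrace"), is(spec, "FilterSpec"))
  fs <- 1000 / trace@dt                       # Hz
  if (spec@lowpass >= fs / 2)
    stop("sampling rate must exceed twice the low-pass corner")
  x <- trace@trace
  apply1 <- function(x, flt)
    if (spec@zero_phase) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  x <- apply1(x, signal::butter(spec@order, spec@lowpass / (fs / 2), "low"))
  if (spec@highpass > 0)
    x <- apply1(x, signal::butter(spec@order, spec@highpass / (fs / 2), "high"))
  new("LfpTrace", trace = x, dt = trace@dt, onset_ms = trace@onset_ms,
      provenance = c(trace@provenance,
                     list(filter = c(spec@highpass, spec@lowpass))))
}

#' Average LFP traces
#'
#' Pointwise mean of consecutive traces (experimentally 10-16 traces are
#' averaged before measuring); all traces must share length and sampling.
#'
#' @param traces list of [LfpTrace-class] objects.
#' @return an [LfpTrace-class]; provenance records `n_averaged`.
#' @export
averageTraces <- function(traces) {
  stopifnot(length(traces) >= 1, all(vapply(traces, is, TRUE, "LfpTrace")))
  n <- vapply(traces, function(x) length(x@trace), 1L)
  dts <- vapply(traces, function(x) x@dt, 1.0)
  if (length(unique(n)) != 1 || length(unique(dts)) != 1)
    stop("traces must share length and sampling interval")
  avg <- Reduce(`+`, lapply(traces, function(x) x@trace)) / length(traces)
  new("LfpTrace", trace = avg, dt = dts[1], onset_ms = traces[[1]]@onset_ms,
      provenance = c(traces[[1]]@provenance,
                     list(n_averaged = length(traces))))
}

#' Write / read an LFP trace as tabular text
#'
#' Plain two-column text (time ms, potential uV) with a commented metadata
#' header (`# key: value`); the round trip is lossless in values (full
#' double precision) and metadata.
#'
#' @param trace an [LfpTrace-class]. @param path file path.
#' @return `writeLfpTrace`: the path, invisibly. `readLfpTrace`: the
#'   [LfpTrace-class].
#' @export
writeLfpTrace <- function(trace, path) {
  meta <- c(dt_ms = trace@dt, onset_ms = trace@onset_ms, unit = "uV")
  prov <- trace@provenance
  prov <- prov[vapply(prov, function(x)
    is.atomic(x) && length(x) == 1 && !is.null(x), TRUE)]
  meta <- c(meta, unlist(prov))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, format, "", digits = 17)), con)
  tvec <- (seq_along(trace@trace) - 1) * trace@dt
  writeLines(sprintf("%.17g\t%.17g", tvec, trace@trace), con)
  invisible(path)
}

#' @rdname writeLfpTrace
#' @export
readLfpTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  meta <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  prov <- meta[setdiff(names(meta), c("dt_ms", "onset_ms", "unit"))]
  prov <- lapply(prov, function(x) {
    y <- suppressWarnings(as.numeric(x)); if (is.na(y)) x else y
  })
  new("LfpTrace", trace = body[[2]], dt = as.numeric(meta$dt_ms),
      onset_ms = as.numeric(meta$onset_ms), provenance = prov)
}

#' Generate a synthetic evoked-LFP fixture set
#'
#' Emulates a set of in-vivo-like evoked LFP recordings: each observation is
#' a repetitive-convolution LFP whose connectivity weights are the true
#' weights perturbed by multiplicative per-trace variation (different
#' recording sites sample slightly different clusters), plus additive
#' Gaussian noise representing the post-averaging residual. The ground truth
#' (weights, per-trace weights, seeds) is returned for closed-loop tests.
#'
#' @param spec a [FixtureSpec-class].
#' @param seed integer seed governing all randomness.
#' @param state a [PlasticityState-class] (release probability used for the
#'   kernels; in vitro measured p = 0.42 by default, as assumed in weight
#'   estimation).
#' @param cluster a [ClusterSpec-class] template (n_cells, inhibition).
#' @param kernels optional precomputed [KernelSet-class] for n_mf 1..4.
#' @return list: `traces` (list of [LfpTrace-class]), `truth` (list with
#'   `weights`, `trace_weights` matrix, `spec`, `seed`), `kernels`.
#' @export
generateFixture <- function(spec = fixtureSpec(), seed = 1,
                            state = plasticityState(0.42, "normal"),
                            cluster = clusterSpec(), kernels = NULL) {
  stopifnot(is(spec, "FixtureSpec"))
  set.seed(seed)
  protocol <- stimulusProtocol("burst", rate_hz = 500, n_spikes = 3L,
                               onset_ms = 10)
  if (is.null(kernels))
    kernels <- generateKernelSet(representativeCombos(cluster@inhibition),
                                 state = state, protocol = protocol)
  jit <- lapply(kernels@kernels[order(kernels@combos[, 1])],
                temporalConvolve, jitter = jitterSpec())
  tw <- matrix(NA_real_, spec@n_traces, 4)
  traces <- vector("list", spec@n_traces)
  for (i in seq_len(spec@n_traces)) {
    w <- spec@weights * pmax(1 + stats::rnorm(4, 0, spec@weight_jitter), 0.05)
    w <- w / sum(w)
    tw[i, ] <- w
    field <- singleNeuronField(jit, w)
    lfp <- spatialConvolve(field, clusterSpec(cluster@n_cells, w,
                                              cluster@inhibition))
    tr <- lfp@trace
    if (spec@tc_delay_ms > 0) {
      k <- round(spec@tc_delay_ms / lfp@dt)
      tr <- tr + c(numeric(k), tr)[seq_along(tr)]
    }
    tr <- tr + stats::rnorm(length(tr), 0, spec@noise_sd)
    traces[[i]] <- new("LfpTrace", trace = tr, dt = lfp@dt,
                       onset_ms = lfp@onset_ms,
                       provenance = list(fixture = TRUE, index = i,
                                         seed = seed))
  }
  list(traces = traces,
       truth = list(weights = spec@weights, trace_weights = tw,
                    spec = spec, seed = seed, state = state),
       kernels = kernels)
}

#' Surface-weighted electrogenic ratio
#'
#' Granule versus Golgi cell contribution to the granular-layer field
#' scales with total electrogenic membrane surface: the cell-count ratio
#' (500:1) times the single-cell surface ratio (3:50) gives a 30-fold larger
#' granule-cell electrogenic surface, which is why the granular-layer LFP is
#' treated as granule-cell generated.
#'
#' @param count_ratio granule:Golgi cell count ratio (default 500).
#' @param surface_ratio granule:Golgi single-cell surface ratio (default 3/50).
#' @return the electrogenic surface ratio (dimensionless).
#' @examples
#' electrogenicSurfaceRatio()  # 30
#' @export
electrogenicSurfaceRatio <- function(count_ratio = 500, surface_ratio = 3 / 50) {
  count_ratio * surface_ratio
}
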