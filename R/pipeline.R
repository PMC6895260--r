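#' Build a fully-resolved pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Any element can
#' be overridden via `...`; unknown names are an error so typos cannot
#' silently fall back to defaults.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bam = NULL,               # input BAM (paired-end, sorted, indexed)
    blacklist = NULL,         # optional blacklist BED path or GRanges
    training_bed = NULL,      # optional user training regions (BED path)
    min_mapq = 30,
    keep_duplicates = FALSE,
    nfr_beta = 100,           # fixed exponential mean (bp)
    em_means = c(200, 400, 600),
    em_sds = c(20, 50, 100),
    em_epsilon = 0.5,
    em_subsample = 0.1,
    nucleosomal_min_length = 100,
    hard_assign_nfr = FALSE,
    bin_size = 10,
    lower_fc = 10,
    upper_fc = 20,
    extension = 5000,
    max_training_regions = 1000,
    n_states = 3,
    zscore_cutoff = 100,
    window_bins = 2500000,
    bw_max_iter = 100,
    bw_tol = 1e-3,
    min_center_length = 200,
    summit_smooth_window = 120,
    min_fragment_length = NULL,  # optional in-silico size selection (bp)
    max_fragment_length = NULL,
    seed = NULL,
    output_prefix = NULL,
    write_tracks = FALSE,
    version = as.character(utils::packageVersion("atachmm"))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

.as_blacklist <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(read_bed(x))
  x
}

#' Run the full peak-calling pipeline
#'
#' Executes, in order: fragment extraction and filtering, fragment-length
#' mixture EM, 4-layer signal track construction with square-root transform,
#' coverage-based training-region selection (or user regions), k-means
#' emission initialization, Baum-Welch refinement, role assignment,
#' masked Viterbi decoding, and gappedPeak assembly with scores and
#' summits. Identical configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()]; alternatively pass overrides through
#'   `...` and leave `config` missing.
#' @param fragments optional pre-loaded fragment `GRanges` (bypasses the BAM
#'   reading stage; must carry seqlengths or `layout` must be given).
#' @param layout optional named vector of chromosome lengths.
#' @param ... overrides forwarded to [pipeline_config()] when `config` is
#'   missing.
#' @return a list with elements `peaks`, `model`, `mixture`, `em_trace`,
#'   `annotation`, `training_regions`, `masked`, `coverage`, `tracks`,
#'   `config`, and (when `output_prefix` is set) `files`.
#' @export
run_pipeline <- function(config = NULL, fragments = NULL, layout = NULL, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (is.null(fragments)) {
    if (is.null(config$bam)) stop("fragio stage: no BAM and no fragments supplied")
    fragments <- tryCatch(
      read_fragments(config$bam, min_mapq = config$min_mapq,
                     drop_duplicates = !config$keep_duplicates),
      error = function(e) stop("fragio stage: ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  if (is.null(layout)) {
    sl <- GenomeInfoDb::seqlengths(fragments)
    if (anyNA(sl)) stop("fragio stage: fragments carry no sequence lengths; supply `layout`")
    layout <- sl
  }
  if (!is.null(config$min_fragment_length)) {
    fragments <- fragments[BiocGenerics::width(fragments) >=
                             config$min_fragment_length]
  }
  if (!is.null(config$max_fragment_length)) {
    fragments <- fragments[BiocGenerics::width(fragments) <=
                             config$max_fragment_length]
  }
  if (length(fragments) == 0L) stop("fragio stage: no fragments after filtering")

  em <- tryCatch(
    fit_em(BiocGenerics::width(fragments),
           init_params = frag_mixture(beta = config$nfr_beta,
                                      means = config$em_means,
                                      sds = config$em_sds),
           epsilon = config$em_epsilon,
           subsample_frac = config$em_subsample,
           nucleosomal_min_length = config$nucleosomal_min_length,
           seed = seed),
    error = function(e) stop("mixture stage: ", conditionMessage(e),
                             call. = FALSE)
  )

  tracks_raw <- build_tracks(fragments, em$mixture, layout,
                             bin_size = config$bin_size,
                             hard_assign_nfr = config$hard_assign_nfr)
  tracks <- sqrt_transform(tracks_raw)
  coverage <- build_coverage(fragments, layout, bin_size = config$bin_size)

  masked <- mask_high_coverage(coverage, zscore_cutoff = config$zscore_cutoff,
                               blacklist = .as_blacklist(config$blacklist))

  training <- tryCatch({
    if (!is.null(config$training_bed)) {
      load_user_training_regions(config$training_bed, layout)
    } else {
      select_training_regions(coverage,
                              lower_fc = config$lower_fc,
                              upper_fc = config$upper_fc,
                              extension = config$extension,
                              max_regions = config$max_training_regions,
                              masked = masked)
    }
  }, error = function(e) stop("training stage: ", conditionMessage(e),
                              call. = FALSE))

  model <- tryCatch({
    spec <- kmeans_init(tracks, training, k = config$n_states,
                        seed = if (is.null(seed)) NULL else seed + 1L)
    spec <- baum_welch(spec, segment_observations(tracks, training),
                       max_iter = config$bw_max_iter, tol = config$bw_tol)
    assign_state_roles(spec)
  }, error = function(e) stop("hmm stage: ", conditionMessage(e),
                              call. = FALSE))

  annotation <- decode_genome(model, tracks, masked = masked,
                              window_bins = config$window_bins)
  peaks <- assemble_peaks(annotation,
                          min_center_length = config$min_center_length)
  peaks <- score_peaks(peaks, coverage)
  peaks <- call_summits(peaks, coverage,
                        smooth_window = config$summit_smooth_window)

  files <- NULL
  if (!is.null(config$output_prefix)) {
    prefix <- config$output_prefix
    files <- list(
      gappedpeak = paste0(prefix, "_peaks.gappedPeak"),
      summits = paste0(prefix, "_summits.bed"),
      model = paste0(prefix, "_model.json")
    )
    write_gappedpeak(peaks, files$gappedpeak)
    write_summits(peaks, files$summits)
    write_model(model, files$model)
    if (isTRUE(config$write_tracks)) {
      files$coverage <- paste0(prefix, "_coverage.bedGraph")
      write_bedgraph(coverage, files$coverage)
      for (layer in LAYERS) {
        f <- paste0(prefix, "_", layer, ".bedGraph")
        write_bedgraph(track_layer(tracks_raw, layer), f)
        files[[paste0("track_", layer)]] <- f
      }
    }
  }

  list(peaks = peaks, model = model, mixture = em$mixture,
       em_trace = em$trace, annotation = annotation,
       training_regions = training, masked = masked,
       coverage = coverage, tracks = tracks, config = config,
       files = files)
}
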