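#' Read a run configuration from YAML
#'
#' A strict-schema YAML file with optional sections `adc`, `codec`,
#' `filters`, `synth`, `analysis` and a top-level `seed`; unknown keys (at
#' either level) are rejected. Each section's keys map onto the
#' corresponding constructor arguments ([adc_config()], [codec_config()],
#' [protocol_spec()]/[signal_params()], [cluster_test_config()]); the
#' `filters` section takes `hp`, `lp`, `bs` preset strings (e.g.
#' `"1.0x4"`, `"45x4"`, `"46-54x6"`, `"off"`) plus `fs_in`.
#'
#' @param path YAML file path.
#' @return A list with fully constructed configuration objects: `adc`,
#'   `codec`, `chain`, `protocol`, `params`, `analysis`, `epoch_s`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  top_known <- c("adc", "codec", "filters", "synth", "analysis", "seed")
  check_keys(cfg, top_known, "top level")
  seed <- cfg$seed %||% 1

  adc <- build_from(cfg$adc, adc_config, "adc")
  codec <- build_from(cfg$codec, codec_config, "codec")

  f <- cfg$filters %||% list()
  check_keys(f, c("hp", "lp", "bs", "fs_in"), "filters")
  fs_in <- f$fs_in %||% 500
  chain <- filter_chain(
    hp = parse_filter_preset("high_pass", f$hp %||% "1.0x4"),
    lp = parse_filter_preset("low_pass", f$lp %||% "45x4"),
    bs = parse_filter_preset("band_stop", f$bs %||% "46-54x6"),
    fs_in = fs_in)

  s <- cfg$synth %||% list()
  check_keys(s, c("block_s", "n_cycles", "first", "fs",
                  names(formals(signal_params))), "synth")
  proto_args <- s[intersect(names(s), c("block_s", "n_cycles", "first"))]
  protocol <- do.call(protocol_spec, proto_args)
  par_args <- s[intersect(names(s), names(formals(signal_params)))]
  if (is.null(par_args$seed)) par_args$seed <- seed
  params <- do.call(signal_params, par_args)

  a <- cfg$analysis %||% list()
  check_keys(a, c("epoch_s", "smoothing_hz",
                  names(formals(cluster_test_config))), "analysis")
  ct_args <- a[intersect(names(a), names(formals(cluster_test_config)))]
  if (is.null(ct_args$seed)) ct_args$seed <- seed
  analysis <- do.call(cluster_test_config, ct_args)

  list(adc = adc, codec = codec, chain = chain, protocol = protocol,
       params = params, analysis = analysis,
       epoch_s = a$epoch_s %||% 30,
       smoothing_hz = a$smoothing_hz %||% 1,
       synth_fs = s$fs %||% 250, seed = seed)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible()
}

build_from <- function(section, ctor, where) {
  section <- section %||% list()
  check_keys(section, names(formals(ctor)), where)
  do.call(ctor, section)
}

#' Parse a filter preset string
#'
#' `"1.0x4"` = 1.0 Hz cutoff, order 4; `"46-54x6"` = band edges 46-54 Hz,
#' total order 6; `"off"` disables the stage.
#'
#' @param kind `"high_pass"`, `"low_pass"` or `"band_stop"`.
#' @param preset Preset string.
#' @return A [filter_spec()].
#' @export
parse_filter_preset <- function(kind, preset) {
  if (identical(preset, "off")) return(filter_spec("off"))
  m <- regmatches(preset, regexec("^([0-9.]+)(?:-([0-9.]+))?x([0-9]+)$",
                                  preset))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse filter preset '%s'", preset), call. = FALSE)
  lo <- as.numeric(m[2]); hi <- m[3]; order <- as.integer(m[4])
  cutoff <- if (nzchar(hi)) c(lo, as.numeric(hi)) else lo
  filter_spec(kind, cutoff, order)
}
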