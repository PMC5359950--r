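# Configuration file parsing and serialisation.

CONFIG_KEYS <- c("treefile_path", "base_genome_path", "base_genome_name",
                 "number_of_variable_sites", "rate_matrix",
                 "base_frequencies", "mutation_clustering",
                 "percent_clustered", "exponential_mean", "indel_rate",
                 "lavalette_a", "lavalette_max", "coverage", "read_length",
                 "fragment_size", "stdev_frag_size", "error_model", "seed",
                 "output_dir", "prefix")

#' Parse a simulation configuration file
#'
#' Flat key=value lines with \code{#} comments. Mandatory keys:
#' \code{treefile_path}, \code{base_genome_path}, \code{base_genome_name}
#' (the anchor tip label) and \code{number_of_variable_sites}. Relative
#' paths are resolved against the config file's directory. Unknown keys
#' produce a warning, not an error. Defaults: no clustering
#' (\code{mutation_clustering=0}), \code{exponential_mean=125},
#' \code{indel_rate=0} (no indels), \code{lavalette_a=1.7},
#' \code{lavalette_max=541}, \code{coverage=20}, \code{read_length=250},
#' \code{fragment_size=500}, \code{stdev_frag_size=50},
#' \code{error_model=default}, \code{output_dir=anchorsim_output},
#' \code{prefix=sim}; \code{seed} absent means entropy-seeded (logged).
#' \code{rate_matrix} is six comma-separated exchangeabilities
#' ac,ag,at,cg,ct,gt, normalised so gt = 1 (defaults to all equal);
#' \code{base_frequencies} optionally overrides the anchor-derived
#' stationary frequencies with four comma-separated values summing to 1.
#' \code{percent_clustered} is a fraction in [0, 1].
#'
#' @param path Path to the configuration file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
parseConfig <- function(path) {
  if (!file.exists(path)) fatal("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  base <- dirname(normalizePath(path))
  kv <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(raw))) next
    if (!grepl("=", raw, fixed = TRUE))
      fatal("line ", ln, ": expected key=value, got '", trimws(raw), "'")
    key <- trimws(sub("=.*$", "", raw))
    val <- trimws(sub("^[^=]*=", "", raw))
    if (!(key %in% CONFIG_KEYS)) {
      warning("unknown configuration key '", key, "' (line ", ln,
              ") ignored")
      next
    }
    kv[[key]] <- list(value = val, line = ln)
  }
  for (must in c("treefile_path", "base_genome_path", "base_genome_name",
                 "number_of_variable_sites"))
    if (is.null(kv[[must]]))
      fatal("mandatory configuration key missing: ", must)

  getNum <- function(key, default, n = 1L) {
    e <- kv[[key]]
    if (is.null(e)) return(default)
    v <- suppressWarnings(as.numeric(strsplit(e$value, ",")[[1]]))
    if (anyNA(v) || length(v) != n)
      fatal("malformed numeric for '", key, "' at line ", e$line, ": ",
            e$value)
    v
  }
  getStr <- function(key, default) {
    e <- kv[[key]]
    if (is.null(e)) default else e$value
  }
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)

  rates <- getNum("rate_matrix", rep(1, 6), 6L)
  if (any(rates <= 0))
    fatal("rate_matrix entries must be positive at line ",
          kv[["rate_matrix"]]$line)
  rates <- rates / rates[6]
  freqs <- getNum("base_frequencies", numeric(0), 4L)
  seed <- getNum("seed", NA_real_)
  nSites <- getNum("number_of_variable_sites", NULL)
  if (nSites != round(nSites) || nSites < 1)
    fatal("number_of_variable_sites must be a positive integer at line ",
          kv[["number_of_variable_sites"]]$line)

  cfg <- new("SimulationConfig",
    treePath = resolve(getStr("treefile_path", NULL)),
    genomePath = resolve(getStr("base_genome_path", NULL)),
    anchorName = getStr("base_genome_name", NULL),
    nSites = as.integer(nSites),
    gtrRates = setNames(rates, c("ac", "ag", "at", "cg", "ct", "gt")),
    baseFreqs = freqs,
    clustering = getNum("mutation_clustering", 0) != 0,
    clusteredFraction = getNum("percent_clustered", 0),
    exponentialMean = getNum("exponential_mean", 125),
    indelRate = getNum("indel_rate", 0),
    lavaletteA = getNum("lavalette_a", 1.7),
    lavaletteMax = as.integer(getNum("lavalette_max", 541)),
    coverage = getNum("coverage", 20),
    readLength = as.integer(getNum("read_length", 250)),
    fragmentMean = getNum("fragment_size", 500),
    fragmentSd = getNum("stdev_frag_size", 50),
    errorModel = getStr("error_model", "default"),
    seed = as.integer(seed),
    outputDir = resolve(getStr("output_dir", "anchorsim_output")),
    prefix = getStr("prefix", "sim"))
  validObject(cfg)
  cfg
}

#' Serialise a configuration back to key=value form
#'
#' Writes every field with its current value; \code{parseConfig} on the
#' result reproduces the configuration (paths are written absolute).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeConfig <- function(config, path) {
  lines <- c(
    paste0("treefile_path=", config@treePath),
    paste0("base_genome_path=", config@genomePath),
    paste0("base_genome_name=", config@anchorName),
    paste0("number_of_variable_sites=", config@nSites),
    paste0("rate_matrix=",
           paste(format(config@gtrRates, digits = 15, trim = TRUE),
                 collapse = ",")),
    if (length(config@baseFreqs))
      paste0("base_frequencies=",
             paste(format(config@baseFreqs, digits = 15, trim = TRUE),
                   collapse = ",")),
    paste0("mutation_clustering=", as.integer(config@clustering)),
    paste0("percent_clustered=", config@clusteredFraction),
    paste0("exponential_mean=", config@exponentialMean),
    paste0("indel_rate=", config@indelRate),
    paste0("lavalette_a=", config@lavaletteA),
    paste0("lavalette_max=", config@lavaletteMax),
    paste0("coverage=", config@coverage),
    paste0("read_length=", config@readLength),
    paste0("fragment_size=", config@fragmentMean),
    paste0("stdev_frag_size=", config@fragmentSd),
    paste0("error_model=", config@errorModel),
    if (!is.na(config@seed)) paste0("seed=", config@seed),
    paste0("output_dir=", config@outputDir),
    paste0("prefix=", config@prefix))
  writeLines(lines, path)
  invisible(path)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n",
      "  tree: ", object@treePath, " (anchor '", object@anchorName, "')\n",
      "  genome: ", object@genomePath, "\n",
      "  variable sites: ", object@nSites,
      if (object@clustering)
        paste0(" (", object@clusteredFraction * 100, "% clustered, mean ",
               object@exponentialMean, " bp)") else " (uniform)", "\n",
      "  indel rate: ", object@indelRate, " per substitution (Lavalette a=",
      object@lavaletteA, ", max ", object@lavaletteMax, ")\n",
      "  reads: ", object@coverage, "x, ", object@readLength, " bp, fragments ",
      object@fragmentMean, " +/- ", object@fragmentSd, "\n", sep = "")
})
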