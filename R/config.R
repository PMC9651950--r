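#' @importFrom yaml read_yaml
NULL

.CONFIG_KEYS <- c("assignment_fraction", "contact_fraction",
                  "contact_dilation", "presyn", "postsyn", "gap_junction",
                  "mask", "block_edge", "halo", "connectivity",
                  "anisotropic_distance", "seed")
.PROFILE_KEYS <- c("prob_threshold", "min_size", "min_seed_separation")
.MASK_KEYS <- c("method", "value", "min_size", "max_gap", "iterations",
                "bridge_radius")

# lenient numeric coercion: strings that parse as numbers are accepted with
# a warning
.coerceNum <- function(x, key) {
  if (is.character(x)) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop(sprintf("config key '%s' must be numeric, got '%s'", key, x),
           call. = FALSE)
    warning(sprintf("config key '%s': coerced string '%s' to %s", key, x, v),
            call. = FALSE)
    return(v)
  }
  if (!is.numeric(x) && !is.logical(x))
    stop(sprintf("config key '%s' must be numeric, got type %s", key,
                 class(x)[1]), call. = FALSE)
  as.numeric(x)
}

.profileFromYaml <- function(y, role, base) {
  if (is.null(y)) return(base)
  unknown <- setdiff(names(y), .PROFILE_KEYS)
  if (length(unknown))
    stop("unknown config key(s) under ", role, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  segmentationProfile(
    role = base@role,
    probThreshold = if (is.null(y$prob_threshold)) base@probThreshold
      else .coerceNum(y$prob_threshold, "prob_threshold"),
    minSizeVoxels = if (is.null(y$min_size)) base@minSizeVoxels
      else as.integer(.coerceNum(y$min_size, "min_size")),
    minSeedSeparation = if (is.null(y$min_seed_separation))
      base@minSeedSeparation
      else as.integer(.coerceNum(y$min_seed_separation, "min_seed_separation")))
}

#' Load a pipeline configuration from YAML
#'
#' Reads the documented YAML schema and fills every unset key with the
#' published default (an empty file yields the full default
#' [pipelineConfig()]).  Unknown keys are rejected by name; numeric values
#' supplied as strings are coerced with a warning.
#'
#' Schema (all keys optional): top-level `assignment_fraction`,
#' `contact_fraction`, `contact_dilation`, `block_edge`, `halo`,
#' `connectivity`, `anisotropic_distance`, `seed`; per-role sections
#' `presyn`/`postsyn`/`gap_junction` with `prob_threshold`, `min_size`,
#' `min_seed_separation`; section `mask` with `method`, `value`,
#' `min_size`, `max_gap`, `iterations`, `bridge_radius`.
#'
#' @param path YAML file.
#' @return a validated [PipelineConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  if (!is.list(y)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(y), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- pipelineConfig()
  num <- function(key, default) {
    if (is.null(y[[key]])) default else .coerceNum(y[[key]], key)
  }
  maskTh <- base@maskThreshold
  bridge <- base@bridge
  maskMin <- base@maskMinSize
  if (!is.null(y$mask)) {
    m <- y$mask
    unknown <- setdiff(names(m), .MASK_KEYS)
    if (length(unknown))
      stop("unknown config key(s) under mask: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!is.null(m$method)) {
      if (!m$method %in% c("otsu", "li", "manual"))
        stop("config mask.method must be otsu, li or manual (got '",
             m$method, "')", call. = FALSE)
      maskTh <- thresholdSpec(m$method,
                              if (is.null(m$value)) NA_real_
                              else .coerceNum(m$value, "mask.value"))
    } else if (!is.null(m$value)) {
      maskTh <- thresholdSpec("manual", .coerceNum(m$value, "mask.value"))
    }
    bridge <- bridgeSpec(
      maxGap = if (is.null(m$max_gap)) bridge@maxGap
        else .coerceNum(m$max_gap, "mask.max_gap"),
      iterations = if (is.null(m$iterations)) bridge@iterations
        else as.integer(.coerceNum(m$iterations, "mask.iterations")),
      bridgeRadius = if (is.null(m$bridge_radius)) bridge@bridgeRadius
        else as.integer(.coerceNum(m$bridge_radius, "mask.bridge_radius")))
    if (!is.null(m$min_size))
      maskMin <- as.integer(.coerceNum(m$min_size, "mask.min_size"))
  }
  cfg <- pipelineConfig(
    assignmentFraction = num("assignment_fraction", base@assignmentFraction),
    contactFraction = num("contact_fraction", base@contactFraction),
    contactDilation = as.integer(num("contact_dilation",
                                     base@contactDilation)),
    presynProfile = .profileFromYaml(y$presyn, "presyn", base@presynProfile),
    postsynProfile = .profileFromYaml(y$postsyn, "postsyn",
                                      base@postsynProfile),
    gapJunctionProfile = .profileFromYaml(y$gap_junction, "gap_junction",
                                          base@gapJunctionProfile),
    maskThreshold = maskTh,
    bridge = bridge,
    maskMinSize = maskMin,
    blockEdge = as.integer(num("block_edge", base@blockEdge)),
    halo = as.integer(num("halo", base@halo)),
    connectivity = as.integer(num("connectivity", base@connectivity)),
    anisotropicDistance = isTRUE(as.logical(num("anisotropic_distance",
                                                base@anisotropicDistance))),
    seed = if (is.null(y$seed)) NA_integer_
      else as.integer(.coerceNum(y$seed, "seed")))
  validObject(cfg)
  cfg
}
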