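# Run configuration: the pipeline's thresholds and sizes in one strict
# YAML-backed structure. Unknown keys are rejected so typos fail loudly.

#' Default run configuration
#'
#' Thresholds: tauPocket 4.0 A (label rule), contactCutoff 8.0 A (protein
#' contacts, strict <), probeCutoff 10.0 A (probe local graph), rProbe 1.4 A
#' (solvent probe), climbRadius 3.0 A (hill-climbing neighborhood),
#' coverageThreshold 0.8 (probe-set batch skip).
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    mode = "residue",
    seed = 1L,
    thresholds = list(tauPocket = 4.0, contactCutoff = 8.0,
                      probeCutoff = 10.0, rProbe = 1.4,
                      climbRadius = 3.0, coverageThreshold = 0.8),
    model = list(numLayers = 4L, hiddenDim = 64L, dScale = 10,
                 aggregation = "sum", residueReduce = "max"),
    train = list(epochs = 30L, nDecoys = 5L, lr = 1e-3, batchSize = 4L),
    synth = list(nComplexes = 20L, nResidues = 30L, pocketSize = 5L,
                 nDecoys = 10L),
    probes = list(latticeCount = 92L, downsampleVoxel = 0, topK = 3L)
  )
}

mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", full)
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      mergeConfig(defaults[[k]], user[[k]], full)
    else user[[k]]
  }
  defaults
}

validateRunConfig <- function(cfg) {
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (!cfg$mode %in% c("residue", "coordinate"))
    stop("mode must be 'residue' or 'coordinate'")
  cfg
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return validated configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- mergeConfig(cfg, user)
  }
  validateRunConfig(cfg)
}

#' Write a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
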