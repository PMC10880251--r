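## Run configuration: every user choice of the standardization workflow, as a
## single serializable object.

#' StdConfig class
#'
#' All user choices for a standardization run: input location and format,
#' ring mode, deduplication, 3D generation, size/shape limits, rule and
#' blocklist files, and the output directory.
#' @exportClass StdConfig
setClass("StdConfig", representation(
  input = "character", format = "character", smilesColumn = "character",
  idColumn = "character", outputDir = "character", ringMode = "character",
  dedup = "logical", make3d = "logical", sizeFilter = "SizeShapeLimits",
  rulesPath = "character", blocklistPath = "character",
  disabledRules = "character"
))

setValidity("StdConfig", function(object) {
  if (!object@ringMode %in% c("aromatic", "kekule"))
    return("ringMode must be 'aromatic' or 'kekule'")
  if (!object@format %in% c("auto", "smi", "csv", "mol", "sdf"))
    return("format must be auto/smi/csv/mol/sdf")
  TRUE
})

setMethod("show", "StdConfig", function(object) {
  cat(sprintf(
    "StdConfig: input=%s (%s), out=%s\n  ring=%s dedup=%s 3d=%s sizeFilter=%s\n",
    object@input, object@format, object@outputDir, object@ringMode,
    object@dedup, object@make3d, object@sizeFilter@enabled))
})

#' Construct a standardization configuration
#'
#' Defaults follow the workflow's conventions: aromatic ring mode, no
#' deduplication, no 3D, size filter off, shipped rule library and blocklist,
#' outputs next to the input file.
#'
#' @param input input structure file.
#' @param format "auto" (detect) or one of smi/csv/mol/sdf.
#' @param smilesColumn,idColumn CSV columns (NA when not applicable).
#' @param outputDir output directory (default: the input's directory).
#' @param ringMode "aromatic" or "kekule".
#' @param dedup collapse InChI duplicates.
#' @param make3d emit optimized 3D structures in the SDF.
#' @param sizeFilter a [sizeLimits()] object.
#' @param rulesPath,blocklistPath rule/blocklist files ("" = shipped default).
#' @param disabledRules rule ids to disable.
#' @return a StdConfig object
#' @export
stdConfig <- function(input = "", format = "auto", smilesColumn = NA_character_,
                      idColumn = NA_character_, outputDir = NA_character_,
                      ringMode = "aromatic", dedup = FALSE, make3d = FALSE,
                      sizeFilter = sizeLimits(), rulesPath = "",
                      blocklistPath = "", disabledRules = character(0)) {
  if (is.na(outputDir) && nzchar(input)) outputDir <- dirname(input)
  new("StdConfig", input = input, format = format,
      smilesColumn = as.character(smilesColumn),
      idColumn = as.character(idColumn),
      outputDir = as.character(outputDir), ringMode = ringMode,
      dedup = dedup, make3d = make3d, sizeFilter = sizeFilter,
      rulesPath = rulesPath, blocklistPath = blocklistPath,
      disabledRules = disabledRules)
}

#' Read a configuration file (YAML)
#'
#' Keys mirror the command-line flags: input, format, smiles_col, id_col,
#' out, ring_mode, dedup, make_3d, size_filter.{enabled,mw_min,mw_max,
#' heavy_min,heavy_max,nano_ratio_max}, transforms.rules_path,
#' transforms.disable, blocklist.path.
#'
#' @param path YAML file.
#' @return a StdConfig object
#' @export
readConfigFile <- function(path) {
  y <- yaml::read_yaml(path)
  sf <- y$size_filter
  lim <- sizeLimits(
    enabled = isTRUE(sf$enabled),
    mwMin = if (is.null(sf$mw_min)) NA else sf$mw_min,
    mwMax = if (is.null(sf$mw_max)) NA else sf$mw_max,
    heavyMin = if (is.null(sf$heavy_min)) 2 else sf$heavy_min,
    heavyMax = if (is.null(sf$heavy_max)) NA else sf$heavy_max,
    nanoRatioMax = if (is.null(sf$nano_ratio_max)) 1.3 else sf$nano_ratio_max)
  stdConfig(
    input = if (is.null(y$input)) "" else y$input,
    format = if (is.null(y$format)) "auto" else y$format,
    smilesColumn = if (is.null(y$smiles_col)) NA_character_ else y$smiles_col,
    idColumn = if (is.null(y$id_col)) NA_character_ else y$id_col,
    outputDir = if (is.null(y$out)) NA_character_ else y$out,
    ringMode = if (is.null(y$ring_mode)) "aromatic" else y$ring_mode,
    dedup = isTRUE(y$dedup), make3d = isTRUE(y$make_3d), sizeFilter = lim,
    rulesPath = if (is.null(y$transforms$rules_path)) "" else y$transforms$rules_path,
    blocklistPath = if (is.null(y$blocklist$path)) "" else y$blocklist$path,
    disabledRules = if (is.null(y$transforms$disable)) character(0)
                    else as.character(y$transforms$disable))
}

#' Write a configuration file (YAML)
#' @param config a StdConfig.
#' @param path output YAML file.
#' @export
writeConfigFile <- function(config, path) {
  sf <- config@sizeFilter
  y <- list(
    input = config@input, format = config@format,
    smiles_col = if (is.na(config@smilesColumn)) NULL else config@smilesColumn,
    id_col = if (is.na(config@idColumn)) NULL else config@idColumn,
    out = config@outputDir, ring_mode = config@ringMode,
    dedup = config@dedup, make_3d = config@make3d,
    size_filter = list(enabled = sf@enabled,
      mw_min = if (is.na(sf@mwMin)) NULL else sf@mwMin,
      mw_max = if (is.na(sf@mwMax)) NULL else sf@mwMax,
      heavy_min = if (is.na(sf@heavyMin)) NULL else sf@heavyMin,
      heavy_max = if (is.na(sf@heavyMax)) NULL else sf@heavyMax,
      nano_ratio_max = if (is.na(sf@nanoRatioMax)) NULL else sf@nanoRatioMax),
    transforms = list(
      rules_path = if (nzchar(config@rulesPath)) config@rulesPath else NULL,
      disable = if (length(config@disabledRules)) config@disabledRules else NULL),
    blocklist = list(
      path = if (nzchar(config@blocklistPath)) config@blocklistPath else NULL))
  yaml::write_yaml(y, path)
  invisible(path)
}
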