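#' Write / read multilayer sample matrices as per-layer TSV files
#'
#' One TSV per layer (first column `sample_id`, then one column per
#' variable; samples in shared order across layers) plus a manifest TSV
#' `layers.tsv` mapping layer name to file path.  The reader verifies that
#' every layer carries the same sample IDs in the same order and that every
#' cell parses as a number, and reports offenders otherwise.
#'
#' @param data a [SampleTensor-class].
#' @param dir output directory (created if needed).
#' @param manifest path to a manifest TSV with columns `layer` and `path`
#'   (paths resolved relative to the manifest's directory).
#' @return `writeLayerMatrices`: the manifest path, invisibly;
#'   `readLayerMatrices`: a [SampleTensor-class].
#' @export
writeLayerMatrices <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nLayers(data))
  for (h in seq_len(nLayers(data))) {
    paths[h] <- paste0("layer_", data@layerNames[h], ".tsv")
    df <- data.frame(sample_id = data@sampleIds,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nVars(data))) df[[data@varNames[i]]] <- data@values[, i, h]
    utils::write.table(df, file.path(dir, paths[h]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  man <- data.frame(layer = data@layerNames, path = paths,
                    stringsAsFactors = FALSE)
  manPath <- file.path(dir, "layers.tsv")
  utils::write.table(man, manPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manPath)
}

#' @rdname writeLayerMatrices
#' @export
readLayerMatrices <- function(manifest) {
  if (!file.exists(manifest)) .stopf("manifest not found: %s", manifest)
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!all(c("layer", "path") %in% names(man))) {
    .stopf("manifest must have columns 'layer' and 'path'")
  }
  base <- dirname(manifest)
  layers <- vector("list", nrow(man))
  sampleIds <- NULL
  varNames <- NULL
  for (h in seq_len(nrow(man))) {
    path <- man$path[h]
    if (!file.exists(path)) path <- file.path(base, man$path[h])
    if (!file.exists(path)) {
      .stopf("layer '%s': file not found (%s)", man$layer[h], man$path[h])
    }
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    if (names(df)[1L] != "sample_id") {
      .stopf("layer '%s': first column must be 'sample_id'", man$layer[h])
    }
    ids <- df$sample_id
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      .stopf("layer '%s': non-numeric cell at row %d, column '%s'",
             man$layer[h], bad[1L], colnames(vals)[bad[2L]])
    }
    if (is.null(sampleIds)) {
      sampleIds <- ids
      varNames <- colnames(vals)
    } else {
      if (!identical(colnames(vals), varNames)) {
        .stopf("layer '%s': variable columns differ from layer '%s'",
               man$layer[h], man$layer[1L])
      }
      if (!identical(ids, sampleIds)) {
        off <- which(ids != sampleIds)
        .stopf("layer '%s': sample IDs misaligned with layer '%s' at rows %s",
               man$layer[h], man$layer[1L],
               paste(utils::head(off, 5L), collapse = ", "))
      }
    }
    layers[[h]] <- num
  }
  vals <- array(0, dim = c(length(sampleIds), length(varNames), nrow(man)))
  for (h in seq_len(nrow(man))) vals[, , h] <- layers[[h]]
  sampleTensor(vals, varNames = varNames, layerNames = man$layer,
               sampleIds = sampleIds)
}
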