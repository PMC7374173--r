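.SCHEMA_VERSION <- "1.1"

#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' Genes as rows (first column = gene id), samples as columns (header
#' row); TSV or CSV chosen by extension (\code{.csv} means comma),
#' optionally gzipped. Ragged rows, non-numeric cells and duplicate
#' sample ids are rejected with the offending line/cell named. Duplicate
#' gene ids are collapsed to the feature with maximal interquartile range
#' when an annotation map is supplied ([collapseFeatures()]), otherwise
#' rejected.
#'
#' @param path file path.
#' @param state declared normalization state of the values.
#' @param annotation optional named character map feature id -> gene id.
#' @param transpose set \code{TRUE} when the file stores samples as rows.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path,
                                 state = c("raw_counts", "size_normalized",
                                           "log2_normalized"),
                                 annotation = NULL, transpose = FALSE) {
    state <- match.arg(state)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    nf <- utils::count.fields(path, sep = sep, quote = "\"",
                              comment.char = "")
    if (length(unique(nf)) > 1L) {
        bad <- which(nf != nf[1L])[1L]
        stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                     bad, path, nf[bad], nf[1L]), call. = FALSE)
    }
    df <- utils::read.delim(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = NULL,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    origSamples <- names(df)[-1L]   # before [.data.frame uniquifies them
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        col <- vals[[j]]
        if (!is.numeric(col)) {
            suppr <- suppressWarnings(as.numeric(col))
            bad <- which(is.na(suppr) & !is.na(col))[1L]
            if (!is.na(bad))
                stop(sprintf("non-numeric cell at row '%s' (line %d), column '%s': '%s'",
                             ids[bad], bad + 1L, colnames(vals)[j],
                             col[bad]), call. = FALSE)
            vals[[j]] <- suppr
        }
    }
    m <- as.matrix(vals)
    storage.mode(m) <- "double"
    rownames(m) <- ids
    colnames(m) <- origSamples      # keep duplicates detectable
    if (transpose) m <- t(m)
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids: ",
             paste(unique(colnames(m)[duplicated(colnames(m))]),
                   collapse = ", "), call. = FALSE)
    if (anyDuplicated(rownames(m))) {
        if (is.null(annotation))
            stop("duplicate gene ids (supply an annotation map to collapse by IQR): ",
                 paste(head(unique(rownames(m)[duplicated(rownames(m))]), 5),
                       collapse = ", "), call. = FALSE)
        # make feature ids unique before collapsing onto the gene ids
        feat <- make.unique(rownames(m))
        ann <- setNames(annotation[rownames(m)], feat)
        rownames(m) <- feat
        return(collapseFeatures(ExpressionMatrix(m, state), ann))
    }
    if (!is.null(annotation))
        return(collapseFeatures(ExpressionMatrix(m, state), annotation))
    ExpressionMatrix(m, state)
}

#' Write an expression matrix as TSV
#'
#' Same layout as [readExpressionMatrix()] reads: genes as rows, first
#' column \code{gene}, samples as columns.
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(em, path) {
    v <- exprValues(em)
    df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write size factors as a sidecar JSON
#'
#' @param sf a \linkS4class{SizeFactors}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSizeFactors <- function(sf, path) {
    jsonlite::write_json(
        list(geneFactors = as.list(geneFactors(sf)),
             sampleFactors = as.list(sampleFactors(sf)),
             retainedGenes = sf@retainedGenes),
        path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    invisible(path)
}

.riskToList <- function(rs) {
    list(geneId = rs@geneId, orientation = rs@orientation,
         bootThresholds = rs@bootThresholds,
         trainValues = as.list(rs@trainValues),
         trainRisk = as.list(rs@trainRisk))
}

.riskFromList <- function(x) {
    new("RiskScoreModel", geneId = x$geneId, orientation = x$orientation,
        bootThresholds = as.numeric(x$bootThresholds),
        trainValues = unlist(x$trainValues),
        trainRisk = unlist(x$trainRisk))
}

.mrsToList <- function(m) {
    list(subtype = m@subtype,
         panel = lapply(m@panel, .riskToList),
         trainMeanRisk = as.list(m@trainMeanRisk),
         trainScore = as.list(m@trainScore),
         curveGrid = m@curveGrid, curveValues = m@curveValues)
}

.mrsFromList <- function(x) {
    new("MRSModel", subtype = x$subtype,
        panel = lapply(x$panel, .riskFromList),
        trainMeanRisk = unlist(x$trainMeanRisk),
        trainScore = unlist(x$trainScore),
        curveGrid = as.numeric(x$curveGrid),
        curveValues = as.numeric(x$curveValues))
}

#' Serialize a trained model to schema-versioned JSON
#'
#' The JSON embeds everything needed to act as a reference set for
#' single-sample prediction: per-gene bootstrap thresholds and training
#' lookup tables, per-subtype score curves, classification thresholds,
#' normalization settings, seed and provenance. Numeric fields are
#' written at full precision so \code{loadModel(saveModel(x))} is an
#' exact round trip. An \linkS4class{MRSModel} (e.g. the Enterocyte
#' score) can be saved the same way.
#'
#' @param model a \linkS4class{ColoTypeModel} or \linkS4class{MRSModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
    if (is(model, "ColoTypeModel")) {
        payload <- list(
            schema = .SCHEMA_VERSION, type = "ColoTypeModel",
            referenceId = model@referenceId, seed = model@seed,
            normalization = model@normalization,
            thresholds = as.list(model@thresholds),
            mrsModels = lapply(model@mrsModels, .mrsToList))
    } else if (is(model, "MRSModel")) {
        payload <- list(schema = .SCHEMA_VERSION, type = "MRSModel",
                        model = .mrsToList(model))
    } else {
        stop("saveModel handles ColoTypeModel or MRSModel", call. = FALSE)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' Load a serialized model
#'
#' Validates the schema version (major version must match; files from an
#' older minor schema load with a warning, missing fields filled with
#' defaults) and reconstructs the S4 object.
#'
#' @param path path to a JSON file written by [saveModel()].
#' @return A \linkS4class{ColoTypeModel} or \linkS4class{MRSModel}.
#' @export
loadModel <- function(path) {
    x <- tryCatch(
        jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE),
        error = function(e)
            stop("not a valid model file: ", conditionMessage(e),
                 call. = FALSE))
    if (is.null(x$schema))
        stop("schema mismatch: no schema version found, expected ",
             .SCHEMA_VERSION, call. = FALSE)
    have <- strsplit(as.character(x$schema), ".", fixed = TRUE)[[1L]]
    want <- strsplit(.SCHEMA_VERSION, ".", fixed = TRUE)[[1L]]
    if (have[1L] != want[1L])
        stop(sprintf("schema mismatch: expected %s, found %s",
                     .SCHEMA_VERSION, x$schema), call. = FALSE)
    if (as.integer(have[2L]) < as.integer(want[2L]))
        warning(sprintf("model file uses older schema %s (current %s); missing fields filled with defaults",
                        x$schema, .SCHEMA_VERSION))
    if (identical(x$type, "MRSModel"))
        return(.mrsFromList(x$model))
    if (!identical(x$type, "ColoTypeModel"))
        stop("schema mismatch: unknown model type '", x$type, "'",
             call. = FALSE)
    norm <- x$normalization
    if (is.null(norm)) norm <- list(pseudocount = 1, conventional = FALSE)
    new("ColoTypeModel",
        mrsModels = lapply(x$mrsModels, .mrsFromList),
        thresholds = unlist(x$thresholds),
        referenceId = x$referenceId %||% "unknown",
        normalization = norm,
        seed = as.integer(x$seed %||% 1L),
        version = as.character(x$schema))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-sample labels from TSV
#'
#' Two columns: sample id and label (header optional but recommended:
#' \code{sample}, \code{label}).
#'
#' @param path file path.
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("label file needs two columns: sample, label", call. = FALSE)
    setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
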