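#' Construct a SummaryStats object from a data.frame
#'
#' Canonical columns are SNP (identifier), EA (effect allele), OA (other
#' allele), EAF (effect-allele frequency, may be NA), BETA (per-allele effect
#' on the trait scale; log-odds for binary traits), SE, P and N (sample
#' size, may be NA). Validation is strict: any invalid row aborts. Use
#' [readSummaryStats()] for tolerant row-level rejection when reading files.
#'
#' @param data data.frame carrying at least SNP, EA, OA, BETA, SE, P; EAF
#'   and N are filled with NA when absent.
#' @return a validated [SummaryStats-class].
#' @examples
#' SummaryStats(data.frame(SNP = "rs1", EA = "A", OA = "G",
#'                         BETA = 0.1, SE = 0.01, P = 1e-9))
#' @export
SummaryStats <- function(data) {
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    if (!"EAF" %in% names(data)) data$EAF <- NA_real_
    if (!"N" %in% names(data)) data$N <- NA_real_
    req <- c("SNP", "EA", "OA", "BETA", "SE", "P")
    miss <- setdiff(req, names(data))
    if (length(miss) > 0L)
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    d <- data[, c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")]
    d$SNP <- as.character(d$SNP)
    d$EA <- toupper(as.character(d$EA))
    d$OA <- toupper(as.character(d$OA))
    for (col in c("EAF", "BETA", "SE", "P", "N"))
        d[[col]] <- as.numeric(d[[col]])
    rownames(d) <- NULL
    new("SummaryStats", data = d)
}

#' Coerce to the canonical summary-statistics data.frame
#'
#' @param x a [SummaryStats-class] (returned as its data.frame) or a
#'   data.frame (validated through [SummaryStats()] first).
#' @return data.frame with columns SNP, EA, OA, EAF, BETA, SE, P, N.
#' @export
asSummaryData <- function(x) {
    if (is(x, "SummaryStats")) return(x@data)
    SummaryStats(x)@data
}

.CANONICAL_COLS <- c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated table with a header row into a [SummaryStats-class].
#' Non-canonical headers are handled through `columnMap`. Rows violating the
#' per-record invariants (invalid alleles, se <= 0, p outside (0,1], eaf
#' outside [0,1]) are rejected with a warning naming each offending row by
#' its line number in the file; valid rows are kept.
#'
#' @param path file path of a tab-delimited table with a header row.
#' @param columnMap optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(SNP = "rsid", BETA = "b")`.
#'   Canonical: SNP, EA, OA, EAF, BETA, SE, P, N.
#' @param sep field separator, tab by default.
#' @return a [SummaryStats-class] holding the accepted rows.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
#'              "rs1\tA\tG\t0.3\t0.10\t0.01\t1e-12\t10000"), tf)
#' readSummaryStats(tf)
#' @export
readSummaryStats <- function(path, columnMap = NULL, sep = "\t") {
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(columnMap)) {
        unknown <- setdiff(names(columnMap), .CANONICAL_COLS)
        if (length(unknown) > 0L)
            stop("columnMap refers to unknown canonical name(s): ",
                 paste(unknown, collapse = ", "))
        for (canon in names(columnMap)) {
            src <- columnMap[[canon]]
            if (!src %in% names(raw))
                stop("configuration error: mapped column '", src,
                     "' (for ", canon, ") not found in ", path)
            names(raw)[names(raw) == src] <- canon
        }
    }
    req <- c("SNP", "EA", "OA", "BETA", "SE", "P")
    miss <- setdiff(req, names(raw))
    if (length(miss) > 0L)
        stop("configuration error: missing required column(s): ",
             paste(miss, collapse = ", "))
    if (!"EAF" %in% names(raw)) raw$EAF <- NA
    if (!"N" %in% names(raw)) raw$N <- NA
    d <- raw[, .CANONICAL_COLS]
    # non-numeric beta/se are a parse error, not a row rejection
    for (col in c("BETA", "SE")) {
        v <- suppressWarnings(as.numeric(d[[col]]))
        bad <- which(is.na(v) & !is.na(d[[col]]) &
                     !toupper(trimws(d[[col]])) %in% c("NA", ""))
        if (length(bad) > 0L)
            stop("parse error: non-numeric ", col, " in row(s) ",
                 paste(bad + 1L, collapse = ", "), " of ", path)
        d[[col]] <- v
    }
    for (col in c("EAF", "P", "N"))
        d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
    d$EA <- toupper(trimws(d$EA)); d$OA <- toupper(trimws(d$OA))
    d$SNP <- as.character(d$SNP)

    reasons <- .badRecordReasons(d)
    # beta/se must additionally be present, not just finite-if-present
    missingCore <- which(is.na(d$BETA) | is.na(d$SE) | is.na(d$P))
    if (length(missingCore) > 0L)
        reasons <- c(reasons,
                     sprintf("row %d: missing beta/se/p", missingCore))
    badRows <- sort(unique(as.integer(sub("^row (\\d+):.*$", "\\1",
                                          reasons))))
    if (length(badRows) > 0L) {
        # +1 converts data row index to file line number (header is line 1)
        rep <- sub("^row (\\d+)", "line \\1", reasons)
        rep <- vapply(seq_along(reasons), function(i) {
            r <- as.integer(sub("^row (\\d+):.*$", "\\1", reasons[i]))
            sub("^row \\d+", sprintf("line %d", r + 1L), reasons[i])
        }, character(1))
        warning("rejected ", length(badRows), " row(s) of ", path, ": ",
                paste(rep, collapse = "; "))
        d <- d[-badRows, , drop = FALSE]
    }
    if (anyDuplicated(d$SNP))
        stop("duplicated snp_id(s) in ", path, ": ",
             paste(unique(d$SNP[duplicated(d$SNP)]), collapse = ", "))
    rownames(d) <- NULL
    new("SummaryStats", data = d)
}

#' Write GWAS summary statistics as tab-separated text
#'
#' Emits the same dialect [readSummaryStats()] consumes: header row with the
#' canonical columns, tab-separated, one row per SNP.
#'
#' @param x a [SummaryStats-class] or canonical data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
    d <- asSummaryData(x)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Construct an LDMatrix
#'
#' @param r2 square symmetric matrix of squared correlations in [0,1] with
#'   unit diagonal.
#' @param snpIds SNP identifiers for the rows/columns; defaults to the
#'   matrix's rownames.
#' @return a validated [LDMatrix-class].
#' @export
LDMatrix <- function(r2, snpIds = rownames(r2)) {
    if (is.null(snpIds)) stop("snpIds required (or rownames on r2)")
    r2 <- as.matrix(r2)
    dimnames(r2) <- list(snpIds, snpIds)
    new("LDMatrix", snpIds = as.character(snpIds), r2 = r2)
}

#' Read an LD matrix from tab-separated text
#'
#' Expects a square matrix with SNP identifiers as both the header row and
#' the first column, as written by [writeLDMatrix()].
#'
#' @param path file path.
#' @return an [LDMatrix-class].
#' @export
readLDMatrix <- function(path) {
    m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
    LDMatrix(as.matrix(m), snpIds = rownames(m))
}

#' Write an LD matrix as tab-separated text
#'
#' @param ld an [LDMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(ld, path) {
    stopifnot(is(ld, "LDMatrix"))
    m <- ld@r2
    dimnames(m) <- list(ld@snpIds, ld@snpIds)
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    invisible(path)
}
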