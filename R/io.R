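## Readers/writers for the plain-text formats the package consumes. All
## files are UTF-8, tab-separated; lines starting with '#' are skipped.
## On disk, coordinates are 0-based half-open (the BED convention); in
## memory everything is a GRanges (1-based closed). The conversion happens
## here and nowhere else.

.readLinesSkip <- function(path) {
    stopifnot(file.exists(path))
    x <- readLines(path, encoding = "UTF-8")
    keep <- !startsWith(x, "#") & nzchar(x)
    list(lines = x[keep], lineno = which(keep))
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3/BED4/BED5; extra columns are ignored with a warning.
#' Column 4 becomes interval names, and column 5 becomes a \code{score}
#' metadata column when \code{expectScore = TRUE}.
#'
#' @param path path to a BED file (0-based half-open coordinates).
#' @param expectScore map column 5 to a numeric \code{score}.
#' @return A \code{GRanges}, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tpeak1\t3.5", bed)
#' readBed(bed, expectScore = TRUE)
#' @export
readBed <- function(path, expectScore = FALSE) {
    lr <- .readLinesSkip(path)
    fields <- strsplit(lr$lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", lr$lineno[which(nf < 3L)[1L]],
             ": fewer than 3 fields")
    if (any(nf > 5L))
        warning("BED columns beyond 5 ignored")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
        stop("malformed BED line ",
             lr$lineno[which(is.na(start) | is.na(end))[1L]],
             ": non-numeric coordinate")
    if (any(start < 0) || any(start >= end))
        stop("invalid interval at line ",
             lr$lineno[which(start < 0 | start >= end)[1L]],
             ": need 0 <= start < end")
    id <- ifelse(nf >= 4L, vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else "", ""), NA_character_)
    score <- NULL
    if (expectScore) {
        if (any(nf < 5L))
            stop("expectScore = TRUE but line ",
                 lr$lineno[which(nf < 5L)[1L]], " has no column 5")
        score <- as.numeric(vapply(fields, `[[`, "", 5L))
        if (anyNA(score))
            stop("non-numeric score at line ",
                 lr$lineno[which(is.na(score))[1L]])
    }
    grFromBed0(chrom, start, end,
               id = if (all(is.na(id))) NULL else id, score = score)
}

#' Write intervals to a BED file
#'
#' @param gr a \code{GRanges}; names become column 4, a \code{score}
#'   metadata column becomes column 5.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
    df <- bed0FromGr(gr)
    if (!is.null(names(gr))) df$name <- names(gr)
    if (!is.null(S4Vectors::mcols(gr)$score)) {
        if (is.null(df$name)) df$name <- "."
        df$score <- S4Vectors::mcols(gr)$score
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path two-column TSV: chromosome name, length in bases.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    lr <- .readLinesSkip(path)
    fields <- strsplit(lr$lines, "\t", fixed = TRUE)
    chrom <- vapply(fields, `[[`, "", 1L)
    len <- as.numeric(vapply(fields, `[[`, "", 2L))
    if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be > 0")
    if (anyDuplicated(chrom)) stop("duplicate chromosome names")
    setNames(len, chrom)
}

#' Write a chrom.sizes file
#' @param sizes named numeric vector of chromosome lengths.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeChromSizes <- function(sizes, path) {
    write.table(data.frame(names(sizes), sizes), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return A \code{DNAStringSet}.
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to a FASTA file
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Parses count blocks of the form produced by JASPAR (a \code{>id name}
#' header followed by four rows \code{A [ ... ]} ... \code{T [ ... ]}) and
#' converts counts to log2 odds against a background with a pseudocount:
#' \code{log2(((count + pseudocount) / (colsum + 4 * pseudocount)) /
#' background)}. The hit threshold is set to \code{thresholdFrac} of each
#' motif's maximum achievable score.
#'
#' @param path path to a JASPAR PFM file (one or more motifs).
#' @param background named base frequencies (default uniform).
#' @param pseudocount per-cell pseudocount (default 1, the JASPAR
#'   convention).
#' @param thresholdFrac fraction of the maximum score used as hit
#'   threshold (default 0.6).
#' @return A named list of [MotifMatrix-class] objects.
#' @export
readJaspar <- function(path, background = c(A = .25, C = .25, G = .25,
                                            T = .25),
                       pseudocount = 1, thresholdFrac = 0.6) {
    stopifnot(file.exists(path), abs(sum(background) - 1) < 1e-9)
    x <- readLines(path, encoding = "UTF-8")
    x <- x[nzchar(x)]
    hdr <- grep("^>", x)
    if (!length(hdr)) stop("no '>' motif headers found")
    out <- list()
    for (h in seq_along(hdr)) {
        from <- hdr[h] + 1L
        to <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(x)
        rows <- x[from:to]
        if (length(rows) != 4L)
            stop("motif block must have exactly 4 count rows")
        id <- sub("^>\\s*", "", x[hdr[h]])
        id <- strsplit(id, "[ \t]+")[[1L]][1L]
        counts <- t(vapply(rows, function(r) {
            r <- gsub("^[ACGTacgt]\\s*", "", r)
            r <- gsub("[][]", " ", r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
        }, numeric(length(strsplit(trimws(gsub("[][]", " ",
            gsub("^[ACGTacgt]\\s*", "", rows[1L]))), "\\s+")[[1L]]))))
        rownames(counts) <- c("A", "C", "G", "T")
        if (any(counts < 0)) stop("negative counts in motif ", id)
        if (any(colSums(counts) == 0))
            stop("all-zero count column in motif ", id)
        out[[id]] <- motifFromCounts(counts, id, background, pseudocount,
                                     thresholdFrac)
    }
    out
}

#' Build a MotifMatrix from a count matrix
#'
#' @param counts 4 x w matrix of base counts (rows A,C,G,T).
#' @param id motif identifier.
#' @inheritParams readJaspar
#' @return A [MotifMatrix-class].
#' @export
motifFromCounts <- function(counts, id,
                            background = c(A = .25, C = .25, G = .25,
                                           T = .25),
                            pseudocount = 1, thresholdFrac = 0.6) {
    rownames(counts) <- c("A", "C", "G", "T")
    prob <- sweep(counts + pseudocount, 2L,
                  colSums(counts) + 4 * pseudocount, "/")
    lo <- log2(sweep(prob, 1L, background[rownames(counts)], "/"))
    m <- new("MotifMatrix", id = id, mat = lo, background = background,
             threshold = 0)
    m@threshold <- thresholdFrac * maxScore(m)
    m
}

#' Read a gene expression matrix
#'
#' TSV with sample ids in the header and gene ids in the first column.
#'
#' @param path input path.
#' @param logTransform replace values by \code{log2(x + 1)}.
#' @return Numeric matrix (genes x samples) with a \code{"normalization"}
#'   attribute (\code{"raw"} or \code{"log2"}).
#' @export
readExpressionMatrix <- function(path, logTransform = FALSE) {
    df <- read.delim(path, check.names = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene ids: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        if (anyNA(v) && !anyNA(vals[[j]]))
            stop("non-numeric value at row ", which(is.na(v))[1L],
                 ", column '", colnames(vals)[j], "'")
        vals[[j]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
    if (any(m < 0)) stop("expression values must be >= 0")
    if (logTransform) m <- log2(m + 1)
    attr(m, "normalization") <- if (logTransform) "log2" else "raw"
    m
}

#' Write an expression matrix as TSV
#' @param m genes x samples numeric matrix.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(m, path) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Normalize an expression matrix
#'
#' Applies \code{log2(x + 1)} and then scales each sample (column) so all
#' column sums equal their mean, the package's "normalized expression"
#' convention for FPKM-like inputs.
#'
#' @param m genes x samples numeric matrix of non-negative values.
#' @return Normalized matrix, \code{"normalization"} attribute set to
#'   \code{"log2-eqsum"}.
#' @export
normalizeExpression <- function(m) {
    stopifnot(all(m >= 0))
    m <- log2(m + 1)
    cs <- colSums(m)
    if (any(cs == 0)) cs[cs == 0] <- 1
    m <- sweep(m, 2L, mean(cs) / cs, "*")
    attr(m, "normalization") <- "log2-eqsum"
    m
}

#' Read a SNP association table
#'
#' TSV with columns \code{chrom}, \code{pos} (0-based), \code{rsid},
#' \code{ref}, \code{alt}, then one p-value column per trait.
#'
#' @param path input path.
#' @param genome optional named vector of chromosome lengths; positions
#'   are checked against it.
#' @return data.frame with a \code{"traits"} attribute naming the trait
#'   columns.
#' @export
readSnpTable <- function(path, genome = NULL) {
    df <- read.delim(path, check.names = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "rsid", "ref", "alt")
    if (!all(need %in% colnames(df)))
        stop("SNP table needs columns: ", paste(need, collapse = ", "))
    traits <- setdiff(colnames(df), need)
    if (!length(traits)) stop("SNP table has no trait p-value columns")
    for (tr in traits) {
        p <- df[[tr]]
        if (any(!is.na(p) & (p <= 0 | p > 1)))
            stop("p-values must lie in (0, 1] (trait '", tr, "')")
    }
    if (!is.null(genome)) {
        bad <- df$pos < 0 | df$pos >= genome[df$chrom]
        if (any(bad, na.rm = TRUE))
            stop("SNP position outside chromosome: ",
                 df$rsid[which(bad)[1L]])
    }
    attr(df, "traits") <- traits
    df
}

#' Write a SNP association table
#' @param snps data.frame as returned by [readSnpTable()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSnpTable <- function(snps, path) {
    write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a directed edge list
#'
#' @param path TSV with columns regulator, target and optionally weight.
#' @param allowSelf permit self-loops.
#' @return data.frame with columns \code{regulator}, \code{target} (and
#'   \code{weight} when present), duplicates removed.
#' @export
readEdgeList <- function(path, allowSelf = FALSE) {
    df <- read.delim(path, check.names = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    colnames(df)[1:2] <- c("regulator", "target")
    df <- df[!duplicated(pairKey(df$regulator, df$target)), , drop = FALSE]
    if (!allowSelf && any(df$regulator == df$target))
        stop("self-loop in edge list: ",
             df$regulator[which(df$regulator == df$target)[1L]])
    rownames(df) <- NULL
    df
}

#' Write a directed edge list
#' @param edges data.frame with columns regulator, target (and optionally
#'   weight).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(edges, path) {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## CRM interval (de)serialization: "chrom:start-end" 0-based half-open,
## semicolon-joined; "." for an empty CRM.
.crmToString <- function(gr) {
    if (length(gr) == 0L) return(".")
    df <- bed0FromGr(gr)
    paste(sprintf("%s:%d-%d", df$chrom, as.integer(df$start),
                  as.integer(df$end)), collapse = ";")
}

.crmFromString <- function(s) {
    if (is.na(s) || s == "." || s == "") return(GenomicRanges::GRanges())
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^(.+):([0-9]+)-([0-9]+)$", parts))
    if (any(lengths(m) != 4L)) stop("malformed CRM interval: ", s)
    chrom <- vapply(m, `[[`, "", 2L)
    start <- as.numeric(vapply(m, `[[`, "", 3L))
    end <- as.numeric(vapply(m, `[[`, "", 4L))
    if (any(start >= end)) stop("invalid CRM interval (start >= end): ", s)
    grFromBed0(chrom, start, end)
}

#' Write a network as a triplet TSV
#'
#' One row per TF-CRM-TG triplet: \code{tf}, \code{tg}, \code{score} (6
#' significant digits) and the CRM as semicolon-joined
#' \code{chrom:start-end} intervals (0-based half-open; \code{.} when
#' empty).
#'
#' @param net a [RegNetwork-class] (or subclass).
#' @param path output path.
#' @param header optional '#'-prefixed provenance lines to prepend.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path, header = NULL) {
    tr <- triplets(net)
    crmStr <- vapply(as.list(crms(net)), .crmToString, "")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("#", header), con)
    writeLines("tf\ttg\tscore\tcrm", con)
    if (nrow(tr))
        writeLines(sprintf("%s\t%s\t%s\t%s", tr$tf, tr$tg,
                           formatC(tr$score, digits = 6, format = "g"),
                           crmStr), con)
    invisible(path)
}

#' Read a triplet-TSV network
#'
#' @param path file written by [writeNetwork()].
#' @param id network identifier to assign.
#' @param weight optional replicate weight; when supplied a
#'   [ReplicateNetwork-class] is returned.
#' @return A [RegNetwork-class] or [ReplicateNetwork-class].
#' @export
readNetwork <- function(path, id = basename(path), weight = NULL) {
    lr <- .readLinesSkip(path)
    lines <- lr$lines
    if (!length(lines) || !startsWith(lines[1L], "tf\t"))
        stop("missing network header line")
    lines <- lines[-1L]
    if (!length(lines)) {
        return(RegNetwork(data.frame(tf = character(0), tg = character(0),
                                     score = numeric(0)),
                          id = id, weight = weight))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L)) stop("malformed network row")
    tr <- data.frame(tf = vapply(fields, `[[`, "", 1L),
                     tg = vapply(fields, `[[`, "", 2L),
                     score = as.numeric(vapply(fields, `[[`, "", 3L)),
                     stringsAsFactors = FALSE)
    crm <- GRangesList(lapply(fields, function(f) .crmFromString(f[[4L]])))
    RegNetwork(tr, crm, id = id, weight = weight)
}
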