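#' Functional profile of one metagenome sample
#'
#' A `FunctionalProfile` holds one sample's map from EC (Enzyme Commission)
#' number to the number of sequencing reads annotated with that molecular
#' function, plus -- once [normalizeProfile()] has been called -- the relative
#' abundance of each function (annotated reads divided by the sample's total
#' read count, which includes unannotated reads).
#'
#' @param sampleID single string identifying the sample.
#' @param counts named non-negative integer vector; names are EC numbers in
#'   dotted four-field form (e.g. `"1.8.1.15"`).
#' @param totalReads total number of reads in the sample (annotated or not);
#'   `NA` until normalization.
#' @param x a `FunctionalProfile`.
#' @return `FunctionalProfile()` returns a new object; `isNormalized()` a
#'   logical scalar.
#' @examples
#' p <- FunctionalProfile("s1", c("1.1.1.1" = 50L, "2.7.7.7" = 10L))
#' p <- normalizeProfile(p, totalReads = 1000)
#' abundances(p)
#' @aliases FunctionalProfile-class isNormalized abundances
#' @export
FunctionalProfile <- function(sampleID, counts = integer(0),
                              totalReads = NA_integer_) {
    .assertScalarString(sampleID, "sampleID")
    counts <- counts[order(names(counts), method = "radix")]
    storage.mode(counts) <- "integer"
    new("FunctionalProfile", sampleID = sampleID, counts = counts,
        totalReads = as.integer(totalReads))
}

#' @rdname FunctionalProfile
#' @export
setMethod("isNormalized", "FunctionalProfile", function(x) {
    length(x@abundances) == length(x@counts) && !is.na(x@totalReads)
})

#' @rdname FunctionalProfile
#' @export
abundances <- function(x) {
    stopifnot(is(x, "FunctionalProfile"))
    if (!isNormalized(x))
        stop("profile '", x@sampleID, "' has not been normalized", call. = FALSE)
    x@abundances
}

#' @rdname FunctionalProfile
#' @export
readCounts <- function(x) {
    stopifnot(is(x, "FunctionalProfile"))
    x@counts
}

setMethod("show", "FunctionalProfile", function(object) {
    cat("FunctionalProfile '", object@sampleID, "': ",
        length(object@counts), " ECs, ",
        if (isNormalized(object))
            sprintf("normalized to %d total reads (annotated fraction %.3g)",
                    object@totalReads, sum(object@abundances))
        else "not normalized",
        "\n", sep = "")
})

#' Read a per-sample EC count file
#'
#' Parses the two-column tab-separated per-sample output of an EC-level read
#' annotator: one row per EC number with its annotated read count. Lines
#' starting with `#` are comments; blank lines are ignored.
#'
#' @param path path to the profile file.
#' @param sampleID sample identifier; defaults to the file name without
#'   extension.
#' @return an unnormalized [FunctionalProfile].
#' @details Malformed EC strings, non-integer counts, rows without exactly two
#'   fields, and duplicated ECs are errors that name the offending line.
#' @export
readProfile <- function(path, sampleID = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("profile file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    ecs <- character(length(keep))
    cnt <- integer(length(keep))
    for (j in seq_along(keep)) {
        i <- keep[j]
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != 2L)
            stop(sprintf("line %d of %s: expected 2 tab-separated fields, got %d",
                         i, path, length(fields)), call. = FALSE)
        ec <- trimws(fields[1L])
        if (!grepl(.EC_REGEX, ec))
            stop(sprintf("line %d of %s: malformed EC identifier '%s'",
                         i, path, ec), call. = FALSE)
        n <- suppressWarnings(as.numeric(trimws(fields[2L])))
        if (is.na(n) || n < 0 || n != floor(n))
            stop(sprintf("line %d of %s: count '%s' is not a non-negative integer",
                         i, path, fields[2L]), call. = FALSE)
        ecs[j] <- ec
        cnt[j] <- as.integer(n)
    }
    if (anyDuplicated(ecs)) {
        dup <- ecs[duplicated(ecs)][1L]
        at <- keep[ecs == dup]
        stop(sprintf("duplicate EC '%s' in %s (lines %s)",
                     dup, path, paste(at, collapse = ", ")), call. = FALSE)
    }
    names(cnt) <- ecs
    FunctionalProfile(sampleID, cnt)
}

#' Normalize a profile by the sample's total read count
#'
#' Relative abundance of a function is its annotated read count divided by the
#' total number of reads in the sample. The total is supplied externally
#' (annotated reads are a small subset of all reads) and must be at least the
#' sum of annotated counts.
#'
#' @param profile a [FunctionalProfile].
#' @param totalReads positive integer total read count.
#' @return the profile with abundances set; counts are preserved.
#' @export
normalizeProfile <- function(profile, totalReads) {
    stopifnot(is(profile, "FunctionalProfile"))
    totalReads <- as.integer(totalReads)
    if (is.na(totalReads) || totalReads <= 0L)
        stop("totalReads must be a positive integer", call. = FALSE)
    if (sum(as.double(profile@counts)) > as.double(totalReads))
        stop(sprintf("annotated reads (%d) exceed totalReads (%d) for sample '%s'",
                     sum(profile@counts), totalReads, profile@sampleID),
             call. = FALSE)
    ab <- as.numeric(profile@counts) / as.numeric(totalReads)
    names(ab) <- names(profile@counts)
    initialize(profile, totalReads = totalReads, abundances = ab)
}

#' EC profile feature container
#'
#' `ECProfileSet` extends `SummarizedExperiment`: rows are EC numbers (the
#' lexicographically sorted union over samples), columns are samples, and the
#' `"abundance"` assay holds relative abundances with exact zeros where an EC
#' was absent from a sample. Column metadata carries the city label (or
#' `"unknown"`), the total read count, and a set tag (`known`, `random`,
#' `outgroup`, ...).
#'
#' @param abundance numeric matrix, ECs x samples, with dimnames.
#' @param city per-sample city labels (recycled if length 1).
#' @param totalReads per-sample total read counts (may be `NA`).
#' @param setTag per-sample set membership tag.
#' @param counts optional integer matrix of annotated read counts.
#' @param metadata list of experiment-level metadata.
#' @param x an `ECProfileSet`.
#' @param samplesAsRows if `TRUE`, `abundanceMatrix` returns the transposed
#'   samples-x-ECs orientation used by the classifiers.
#' @param ... unused.
#' @return `ECProfileSet()` returns the container; accessors return the
#'   corresponding vectors/matrix.
#' @aliases ecUniverse cityLabels setTags totalReads abundanceMatrix
#' @export
ECProfileSet <- function(abundance, city = "unknown", totalReads = NA_real_,
                         setTag = "known", counts = NULL, metadata = list()) {
    if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
        stop("abundance matrix must have EC row names and sample column names",
             call. = FALSE)
    ord <- order(rownames(abundance), method = "radix")
    abundance <- abundance[ord, , drop = FALSE]
    asy <- list(abundance = abundance)
    if (!is.null(counts))
        asy$counts <- counts[rownames(abundance), , drop = FALSE]
    cd <- S4Vectors::DataFrame(
        city = as.character(rep_len(city, ncol(abundance))),
        total_reads = as.numeric(rep_len(totalReads, ncol(abundance))),
        set_tag = as.character(rep_len(setTag, ncol(abundance))),
        row.names = colnames(abundance)
    )
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = asy, colData = cd, metadata = metadata)
    new("ECProfileSet", se)
}

#' @rdname ECProfileSet
#' @export
setMethod("ecUniverse", "ECProfileSet", function(x) rownames(x))

#' @rdname ECProfileSet
#' @export
setMethod("cityLabels", "ECProfileSet", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$city, colnames(x))
})

#' @rdname ECProfileSet
#' @export
setMethod("setTags", "ECProfileSet", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$set_tag, colnames(x))
})

#' @rdname ECProfileSet
#' @export
setMethod("totalReads", "ECProfileSet", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$total_reads, colnames(x))
})

#' @rdname ECProfileSet
#' @export
setMethod("abundanceMatrix", "ECProfileSet",
    function(x, samplesAsRows = FALSE) {
        a <- SummarizedExperiment::assay(x, "abundance")
        if (samplesAsRows) t(a) else a
    })

setMethod("show", "ECProfileSet", function(object) {
    tags <- table(setTags(object))
    cat("ECProfileSet: ", ncol(object), " samples x ", nrow(object),
        " ECs\n  set tags: ",
        paste(sprintf("%s (%d)", names(tags), tags), collapse = ", "),
        "\n  cities: ",
        paste(utils::head(sort(unique(cityLabels(object))), 10L), collapse = ", "),
        "\n", sep = "")
})

#' Assemble profiles into a feature matrix
#'
#' Builds an [ECProfileSet] over the union of all ECs seen in the given
#' normalized profiles, in lexicographic column order, filling ECs absent from
#' a sample with exact zeros.
#'
#' @param profiles list of normalized [FunctionalProfile] objects.
#' @param metadata optional data.frame with columns `sample_id`, `city`,
#'   `total_reads`, `set_tag`; matched to profiles by `sample_id`. Profiles
#'   without a metadata row get city `"unknown"`, tag `"known"`.
#' @return an [ECProfileSet] with `abundance` and `counts` assays.
#' @export
buildFeatureMatrix <- function(profiles, metadata = NULL) {
    if (!length(profiles)) stop("no profiles given", call. = FALSE)
    norm <- vapply(profiles, isNormalized, logical(1L))
    if (!all(norm)) {
        bad <- vapply(profiles[!norm], function(p) p@sampleID, character(1L))
        stop("unnormalized profile(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
    ids <- vapply(profiles, function(p) p@sampleID, character(1L))
    if (anyDuplicated(ids))
        stop("duplicate sample IDs: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    universe <- sort(unique(unlist(lapply(profiles, function(p) names(p@counts)),
                                   use.names = FALSE)), method = "radix")
    if (length(universe) > MAX_ANNOTATABLE_ECS)
        stop("EC union exceeds the ", MAX_ANNOTATABLE_ECS, " annotatable maximum",
             call. = FALSE)
    a <- matrix(0, nrow = length(universe), ncol = length(profiles),
                dimnames = list(universe, ids))
    cnt <- matrix(0L, nrow = length(universe), ncol = length(profiles),
                  dimnames = list(universe, ids))
    for (j in seq_along(profiles)) {
        p <- profiles[[j]]
        a[names(p@abundances), j] <- p@abundances
        cnt[names(p@counts), j] <- p@counts
    }
    city <- rep("unknown", length(ids))
    tag <- rep("known", length(ids))
    tot <- vapply(profiles, function(p) as.numeric(p@totalReads), numeric(1L))
    if (!is.null(metadata)) {
        m <- match(ids, metadata$sample_id)
        hit <- !is.na(m)
        if ("city" %in% names(metadata)) city[hit] <- as.character(metadata$city[m[hit]])
        if ("set_tag" %in% names(metadata)) tag[hit] <- as.character(metadata$set_tag[m[hit]])
    }
    ECProfileSet(a, city = city, totalReads = tot, setTag = tag, counts = cnt)
}

#' Read a sample set from per-sample profile files plus a metadata table
#'
#' @param profileDir directory containing `<sample_id>.tsv` profile files.
#' @param metadataFile CSV with header `sample_id,city,total_reads,set_tag`.
#' @return an [ECProfileSet].
#' @export
readSampleSet <- function(profileDir, metadataFile) {
    meta <- utils::read.csv(metadataFile, stringsAsFactors = FALSE)
    needed <- c("sample_id", "city", "total_reads", "set_tag")
    missing <- setdiff(needed, names(meta))
    if (length(missing))
        stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    profiles <- lapply(seq_len(nrow(meta)), function(i) {
        p <- readProfile(file.path(profileDir, paste0(meta$sample_id[i], ".tsv")),
                         sampleID = meta$sample_id[i])
        normalizeProfile(p, meta$total_reads[i])
    })
    buildFeatureMatrix(profiles, metadata = meta)
}

#' Export and re-import a feature matrix as TSV
#'
#' The export is samples-as-rows: first column `sample_id`, then one column
#' per EC. Values are written with 17 significant digits so that a round trip
#' reproduces the doubles bit-exactly.
#'
#' @param x an [ECProfileSet].
#' @param path output/input TSV path.
#' @param city,totalReads,setTag metadata for re-import (defaults as in
#'   [ECProfileSet()]).
#' @return `writeFeatureMatrix` returns `path` invisibly; `readFeatureMatrix`
#'   an [ECProfileSet].
#' @export
writeFeatureMatrix <- function(x, path) {
    stopifnot(is(x, "ECProfileSet"))
    m <- abundanceMatrix(x, samplesAsRows = TRUE)
    header <- paste(c("sample_id", colnames(m)), collapse = "\t")
    rows <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, character(1L))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path, city = "unknown", totalReads = NA_real_,
                              setTag = "known") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    ids <- tab[[1L]]
    m <- vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tab))
    dimnames(m) <- list(ids, names(tab)[-1L])
    ECProfileSet(t(m), city = city, totalReads = totalReads, setTag = setTag)
}

# Project a feature container onto a training EC universe: ECs unseen in
# training are dropped; training ECs absent from the samples contribute zeros.
# Returns a samples x ECs matrix aligned with `universe`.
.projectMatrix <- function(x, universe) {
    m <- if (is(x, "ECProfileSet")) abundanceMatrix(x, samplesAsRows = TRUE)
         else as.matrix(x)
    out <- matrix(0, nrow = nrow(m), ncol = length(universe),
                  dimnames = list(rownames(m), universe))
    shared <- intersect(colnames(m), universe)
    out[, shared] <- m[, shared, drop = FALSE]
    out
}

#' Project samples onto a training EC universe
#'
#' Model features are frozen at training time: when scoring new samples, ECs
#' not in the training universe are dropped and training ECs absent from the
#' new samples are set to zero.
#'
#' @param x an [ECProfileSet] or samples-x-ECs matrix.
#' @param universe character vector of training ECs (ordered).
#' @return a samples x ECs numeric matrix whose columns are exactly `universe`.
#' @export
projectProfiles <- function(x, universe) .projectMatrix(x, universe)
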