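#' Read a per-cytosine bisulfite count table
#'
#' Reads a tab-delimited table of per-cytosine bisulfite counts in the
#' style of a BSMAP methratio / Bismark CX report: one row per cytosine
#' with columns `chrom`, `pos`, `strand` (+/-), `context` (CG/CHG/CHH),
#' `n_meth` (reads supporting methylation) and `n_total` (total reads).
#' A single leading `#`-prefixed header line is permitted and skipped.
#'
#' Positions are converted to the package's internal 0-based convention
#' when `one_based_input = TRUE`. Rows with `n_total = 0` (uncovered
#' cytosines) are retained; downstream analyses filter on coverage
#' explicitly.
#'
#' @param path path to a TSV file.
#' @param one_based_input logical; set when positions on disk are 1-based.
#' @return a `data.table` with columns chrom, pos, strand, context,
#'   n_meth, n_total, in file order.
#' @export
read_cytosine_table <- function(path, one_based_input = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(empty_cytosine_table())
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  nlines <- length(readLines(path))
  if (nlines <= skip) return(empty_cytosine_table())
  dt <- tryCatch(
    fread(path, sep = "\t", header = FALSE, skip = skip, fill = FALSE,
          colClasses = list(character = c(1, 3, 4), integer = c(2, 5, 6))),
    error = function(e) stop("malformed cytosine table '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) != 6L)
    stop("malformed cytosine table '", path, "': expected 6 columns, found ",
         ncol(dt))
  setnames(dt, CYTO_COLS)
  line_no <- function(i) i + skip   # 1-based file line of data row i
  bad <- which(!dt$context %in% CONTEXTS)
  if (length(bad))
    stop("parse error at line ", line_no(bad[1]), ": unknown context token '",
         dt$context[bad[1]], "' (allowed: ", paste(CONTEXTS, collapse = ", "), ")")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("parse error at line ", line_no(bad[1]), ": strand must be + or -")
  bad <- which(dt$n_meth < 0L | dt$n_total < 0L | dt$n_meth > dt$n_total)
  if (length(bad))
    stop("parse error at line ", line_no(bad[1]), ": need 0 <= n_meth (",
         dt$n_meth[bad[1]], ") <= n_total (", dt$n_total[bad[1]], ")")
  if (one_based_input) dt[, pos := pos - 1L]
  bad <- which(dt$pos < 0L)
  if (length(bad))
    stop("parse error at line ", line_no(bad[1]), ": negative position")
  dt[]
}

#' Write a per-cytosine bisulfite count table
#'
#' Inverse of [read_cytosine_table()]: tab-delimited, one `#`-prefixed
#' header line, positions written 1-based when `one_based = TRUE`.
#'
#' @param records cytosine record table.
#' @param path output path.
#' @param one_based write 1-based positions.
#' @return `path`, invisibly.
#' @export
write_cytosine_table <- function(records, path, one_based = FALSE) {
  records <- validate_cytosines(records)
  out <- copy(records[, CYTO_COLS, with = FALSE])
  if (one_based) out[, pos := pos + 1L]
  writeLines(paste0("#", paste(CYTO_COLS, collapse = "\t")), path)
  if (nrow(out))
    fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read genomic features (genes, lncRNAs, transposable elements)
#'
#' Supported dialects:
#' * `"GFF3"` (1-based inclusive on disk): rows of type `gene` map to kind
#'   `PCG`, `lnc_RNA`/`lncRNA` to `lncRNA` (attribute `subkind=lincRNA`
#'   marks the intergenic subclass) and `transposable_element` to `TE`
#'   (attributes `te_class`, `te_order`). Other row types are ignored.
#' * `"BED"` (0-based half-open): intervals are imported as TEs with ids
#'   from the name column; class/order are left `NA` unless the name looks
#'   like `class:order` (e.g. `I:Gypsy`).
#' * `"TE-TSV"`: tab-delimited columns `chrom, start (0-based), end,
#'   class, order` with optional 6th `id` column; `class` must be I or II
#'   and `order` must belong to [TE_ORDERS].
#'
#' All coordinates are normalised to 0-based half-open in memory.
#'
#' @param path input file.
#' @param format one of `"GFF3"`, `"BED"`, `"TE-TSV"`.
#' @return feature `data.table` with columns id, chrom, start, end,
#'   strand, kind, subkind, te_class, te_order.
#' @export
read_features <- function(path, format = c("GFF3", "BED", "TE-TSV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  ft <- switch(format,
    "GFF3" = .read_features_gff3(path),
    "BED" = .read_features_bed(path),
    "TE-TSV" = .read_features_tetsv(path))
  validate_features(ft)
}

.read_features_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  kind <- rep(NA_character_, length(g))
  kind[type == "gene"] <- "PCG"
  kind[type %in% c("lnc_RNA", "lncRNA")] <- "lncRNA"
  kind[type == "transposable_element"] <- "TE"
  keep <- !is.na(kind)
  g <- g[keep]; kind <- kind[keep]
  mc <- S4Vectors::mcols(g)
  getcol <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(g))
  id <- getcol("ID")
  if (anyNA(id)) id[is.na(id)] <- sprintf("feat%06d", which(is.na(id)))
  strand <- as.character(BiocGenerics::strand(g))
  strand[strand == "*"] <- "."
  subkind <- getcol("subkind")
  subkind[kind == "lncRNA" & is.na(subkind)] <- "other"
  subkind[kind != "lncRNA"] <- NA_character_
  data.table(id = id,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = BiocGenerics::start(g) - 1L,
             end = BiocGenerics::end(g),
             strand = strand, kind = kind, subkind = subkind,
             te_class = ifelse(kind == "TE", getcol("te_class"), NA_character_),
             te_order = ifelse(kind == "TE", getcol("te_order"), NA_character_))
}

.read_features_bed <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  id <- g$name
  if (is.null(id) || anyNA(id)) {
    auto <- sprintf("TE%05d", seq_along(g))
    id <- if (is.null(id)) auto else ifelse(is.na(id), auto, id)
  }
  cls <- rep(NA_character_, length(g)); ord <- rep(NA_character_, length(g))
  pat <- grepl("^(I|II):", id)
  cls[pat] <- sub(":.*$", "", id[pat])
  ord[pat] <- sub("^[^:]+:", "", id[pat])
  ord[!is.na(ord) & !ord %in% TE_ORDERS] <- NA_character_
  strand <- as.character(BiocGenerics::strand(g))
  strand[strand == "*"] <- "."
  data.table(id = id,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = BiocGenerics::start(g) - 1L,
             end = BiocGenerics::end(g),
             strand = strand, kind = "TE", subkind = NA_character_,
             te_class = cls, te_order = ord)
}

.read_features_tetsv <- function(path) {
  if (file.size(path) == 0L) return(empty_feature_table())
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  dt <- fread(path, sep = "\t", header = FALSE, skip = skip, fill = FALSE)
  if (!ncol(dt) %in% 5:6)
    stop("TE-TSV '", path, "': expected 5 or 6 columns (chrom, start, end, ",
         "class, order[, id]), found ", ncol(dt))
  setnames(dt, c("chrom", "start", "end", "te_class", "te_order",
                 if (ncol(dt) == 6L) "id"))
  bad <- which(!dt$te_class %in% c("I", "II"))
  if (length(bad))
    stop("TE-TSV line ", bad[1] + skip, ": class '", dt$te_class[bad[1]],
         "' not in {I, II}")
  bad <- which(!dt$te_order %in% TE_ORDERS)
  if (length(bad))
    stop("TE-TSV line ", bad[1] + skip, ": unknown TE order '",
         dt$te_order[bad[1]], "'; allowed: ", paste(TE_ORDERS, collapse = ", "))
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("TE-TSV line ", bad[1] + skip, ": end <= start")
  if (!"id" %in% names(dt)) dt[, id := sprintf("TE%05d", .I)]
  dt[, .(id, chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), strand = ".", kind = "TE",
         subkind = NA_character_, te_class, te_order)]
}

#' Write genomic features
#'
#' Writes a feature table as GFF3 (any kinds; attributes `subkind`,
#' `te_class`, `te_order` carried through so a read round-trips) or as the
#' TE-TSV dialect (TE rows only).
#'
#' @param features feature table as returned by [read_features()].
#' @param path output path.
#' @param format `"GFF3"` or `"TE-TSV"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("GFF3", "TE-TSV")) {
  format <- match.arg(format)
  features <- validate_features(features)
  if (format == "TE-TSV") {
    te <- features[kind == "TE"]
    writeLines("#chrom\tstart\tend\tclass\torder\tid", path)
    if (nrow(te))
      fwrite(te[, .(chrom, start, end, te_class, te_order, id)], path,
             sep = "\t", col.names = FALSE, append = TRUE)
    return(invisible(path))
  }
  type <- c(PCG = "gene", lncRNA = "lnc_RNA", TE = "transposable_element")
  g <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand == ".", "*", features$strand))
  g$source <- "methploid"
  g$type <- type[features$kind]
  g$ID <- features$id
  g$subkind <- features$subkind
  g$te_class <- features$te_class
  g$te_order <- features$te_order
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Write DMR calls as BED6 and TSV
#'
#' Emits `<path>.bed` (name = `context:direction`, score =
#' `round(1000 * |delta|)`, strand `.`) and `<path>.tsv` with columns
#' chrom, start, end, context, ratio_2x, ratio_4x, delta, q, direction,
#' annotation. Both files are sorted by (chrom, start); an empty DMR set
#' produces a headers-only TSV and an empty BED.
#'
#' @param dmrs DMR table from [call_dmrs()] (optionally annotated by
#'   [annotate_dmr_location()]).
#' @param path output path prefix (".bed"/".tsv" appended).
#' @return character vector of the two paths, invisibly.
#' @export
write_dmr_output <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  bed_path <- paste0(path, ".bed")
  tsv_path <- paste0(path, ".tsv")
  header <- "#chrom\tstart\tend\tcontext\tratio_2x\tratio_4x\tdelta\tq\tdirection\tannotation"
  if (!nrow(dmrs)) {
    writeLines(character(0), bed_path)
    writeLines(header, tsv_path)
    return(invisible(c(bed_path, tsv_path)))
  }
  need <- c("chrom", "start", "end", "context", "ratio_2x", "ratio_4x",
            "delta", "q", "direction")
  miss <- setdiff(need, names(dmrs))
  if (length(miss)) stop("DMR table lacks column(s): ", paste(miss, collapse = ", "))
  dmrs <- copy(dmrs)
  if (!"annotation" %in% names(dmrs)) dmrs[, annotation := NA_character_]
  setorder(dmrs, chrom, start)
  bed <- dmrs[, sprintf("%s\t%d\t%d\t%s:%s\t%d\t.", chrom, start, end,
                        context, direction, as.integer(round(1000 * abs(delta))))]
  writeLines(bed, bed_path)
  writeLines(header, tsv_path)
  fwrite(dmrs[, .(chrom, start, end, context,
                  ratio_2x = signif(ratio_2x, 6), ratio_4x = signif(ratio_4x, 6),
                  delta = signif(delta, 6), q = signif(q, 6),
                  direction, annotation)],
         tsv_path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(c(bed_path, tsv_path))
}

#' Read an expression table
#'
#' Tab-delimited long-format FPKM table with columns `id`, `cytotype`
#' (2x/4x), `replicate`, `fpkm`, one `#`-prefixed header line.
#'
#' @param path input TSV.
#' @return `data.table` with those columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  dt <- fread(path, sep = "\t", header = FALSE, skip = skip,
              col.names = c("id", "cytotype", "replicate", "fpkm"))
  if (any(dt$fpkm < 0)) stop("expression table '", path, "': negative FPKM")
  if (any(!dt$cytotype %in% c("2x", "4x")))
    stop("expression table '", path, "': cytotype must be 2x or 4x")
  dt[]
}

#' Write an expression table
#' @param expr long-format expression table (id, cytotype, replicate, fpkm).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  expr <- as.data.table(expr)
  writeLines("#id\tcytotype\treplicate\tfpkm", path)
  if (nrow(expr))
    fwrite(expr[, .(id, cytotype, replicate, fpkm)], path, sep = "\t",
           col.names = FALSE, append = TRUE)
  invisible(path)
}
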