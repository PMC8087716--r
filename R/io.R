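#' Read a FASTA file into a named vector of sequences
#'
#' Sequences are uppercased; the record name is the header token before the
#' first whitespace. Backed by [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(setNames(character(0), character(0)))
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("malformed FASTA header at line %d of '%s'",
                  nonblank[1], path))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) abort("duplicate FASTA record names")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Consumes `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` rows (other feature types are ignored); children are
#' linked through their `Parent` attribute. Coordinates are converted from
#' GFF3 1-based closed to the package's internal 0-based half-open
#' convention on read. The TSS is strand aware: the gene start for `+`
#' genes, the gene end for `-` genes.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `tss` (0-based position of the TSS base), `start`, `end`
#'   (0-based half-open gene span) and list-columns `exons`, `cds`, `utr5`,
#'   `utr3`, each a tibble of 0-based half-open intervals sorted by start.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start1 = GenomicRanges::start(gr),
    end1 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent %||% rep(list(character(0)), length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  keep_types <- c("gene", "mRNA", "exon", "CDS",
                  "five_prime_UTR", "three_prime_UTR")
  df <- df[df$type %in% keep_types, , drop = FALSE]

  genes <- df[df$type == "gene", , drop = FALSE]
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene row without a '+'/'-' strand")
  }
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  # transcript -> gene map; children may also point directly at genes
  tx2gene <- setNames(mrna$parent, mrna$id)
  known_parents <- c(genes$id, mrna$id)

  children <- df[!df$type %in% c("gene", "mRNA"), , drop = FALSE]
  unknown <- !(children$parent %in% known_parents)
  if (any(unknown)) {
    warn(sprintf("skipping %d GFF3 feature(s) with unknown Parent",
                 sum(unknown)))
    children <- children[!unknown, , drop = FALSE]
  }
  children$gene_id <- ifelse(children$parent %in% names(tx2gene),
                             unname(tx2gene[children$parent]),
                             children$parent)

  ivl_list <- function(gid, type) {
    sub <- children[children$gene_id == gid & children$type == type, ,
                    drop = FALSE]
    sub <- sub[order(sub$start1), , drop = FALSE]
    tibble(start = sub$start1 - 1L, end = sub$end1)
  }

  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    start0 <- g$start1 - 1L
    end0 <- g$end1
    tibble(
      gene_id = g$id,
      chrom = g$chrom,
      strand = g$strand,
      tss = if (g$strand == "+") start0 else end0 - 1L,
      start = start0,
      end = end0,
      exons = list(ivl_list(g$id, "exon")),
      cds = list(ivl_list(g$id, "CDS")),
      utr5 = list(ivl_list(g$id, "five_prime_UTR")),
      utr3 = list(ivl_list(g$id, "three_prime_UTR"))
    )
  })
  arrange(bind_rows(out), .data$chrom, .data$start, .data$gene_id)
}

#' Write gene models to GFF3
#'
#' Deterministic formatter (byte-stable for identical input) emitting one
#' gene + one mRNA row per model and the exon/CDS/UTR children, converting
#' internal 0-based half-open intervals back to GFF3 1-based closed.
#'
#' @param models Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  row_fmt <- function(chrom, type, s0, e0, strand, attrs) {
    sprintf("%s\tchillomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e0, strand, attrs)
  }
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
               row_fmt(g$chrom, "gene", g$start, g$end, g$strand,
                       paste0("ID=", gid)),
               row_fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
                       paste0("ID=", tid, ";Parent=", gid)))
    emit <- function(type, tbl) {
      if (nrow(tbl) == 0L) return(character(0))
      vapply(seq_len(nrow(tbl)), function(j) {
        row_fmt(g$chrom, type, tbl$start[j], tbl$end[j], g$strand,
                paste0("ID=", tid, ".", type, j, ";Parent=", tid))
      }, character(1))
    }
    lines <- c(lines,
               emit("exon", g$exons[[1]]),
               emit("five_prime_UTR", g$utr5[[1]]),
               emit("CDS", g$cds[[1]]),
               emit("three_prime_UTR", g$utr3[[1]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ peak file
#'
#' BED coordinates are 0-based half-open and preserved as such. An optional
#' 4th column is the peak name, 5th the score.
#'
#' @param path Path to a BED file.
#' @param replicate Optional replicate identifier attached to every peak.
#' @return Tibble with `chrom`, `start`, `end`, and when present `name`,
#'   `score`, plus `replicate`.
#' @export
read_bed <- function(path, replicate = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  replicate = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("BED line %d has fewer than 3 fields",
                  which(nf < 3L)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-integer BED coordinate at line %d",
                  which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    abort(sprintf("invalid BED interval (start >= end or negative) at line %d",
                  bad[1]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 5L)) {
    out$score <- as.numeric(vapply(fields, `[[`, character(1), 5L))
  }
  out$replicate <- as.character(replicate)
  out
}

#' Write peaks to BED
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  cols <- list(peaks$chrom, peaks$start, peaks$end)
  if ("name" %in% names(peaks)) {
    cols <- c(cols, list(peaks$name))
    if ("score" %in% names(peaks)) cols <- c(cols, list(peaks$score))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' The alphabet must be ACGT; rows off unit sum by more than 0.01 raise an
#' error, smaller deviations are renormalized with a warning.
#'
#' @param path Path to a MEME minimal-format motif file.
#' @return Tibble with `motif_id`, `width` and a list-column `pwm` of
#'   L x 4 probability matrices (columns A, C, G, T).
#' @export
read_meme_motifs <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    abort("not a MEME minimal-format file (missing 'MEME version')")
  }
  alpha <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha) && !grepl("ACGT", alpha[1])) {
    abort("only the ACGT alphabet is supported")
  }
  starts <- grep("^MOTIF\\b", lines)
  motifs <- purrr::map(seq_along(starts), function(k) {
    i <- starts[k]
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) {
      abort(sprintf("motif '%s' lacks a letter-probability matrix", name))
    }
    rows <- list()
    j <- j + 1L
    while (j <= length(lines)) {
      tl <- trimws(lines[j])
      if (!nzchar(tl) || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    m <- do.call(rbind, rows)
    colnames(m) <- DNA_BASES
    if (any(m < 0)) abort(sprintf("negative probability in motif '%s'", name))
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 0.01)) {
      abort(sprintf("motif '%s' row sums deviate from 1 by more than 0.01",
                    name))
    }
    if (any(abs(rs - 1) > 1e-6)) {
      warn(sprintf("renormalizing motif '%s' rows to unit sum", name))
      m <- m / rs
    }
    tibble(motif_id = name, width = nrow(m), pwm = list(m))
  })
  bind_rows(motifs)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs Motif tibble as returned by [read_meme_motifs()].
#' @param path Output path.
#' @param background Background frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f",
                     background[1], background[2], background[3],
                     background[4]), "")
  for (i in seq_len(nrow(motifs))) {
    m <- motifs$pwm[[i]]
    lines <- c(lines,
               paste("MOTIF", motifs$motif_id[i]),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m)),
               apply(m, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                               r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `condition`, `replicate`.
#' @return Tibble with those columns, `replicate` as integer.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  stopifnot(all(c("sample", "condition", "replicate") %in% names(sheet)))
  as_tibble(sheet)
}

#' Read a feature-by-sample count table
#'
#' First column is the feature id, remaining columns are samples; every
#' sample column must be matched in the sample sheet and every cell must be
#' a non-negative integer.
#'
#' @param path TSV count table.
#' @param sample_sheet Tibble with `sample`, `condition`, `replicate`.
#' @return Tibble with `feature_id` plus one integer column per sample.
#' @export
read_count_table <- function(path, sample_sheet) {
  tbl <- readr::read_tsv(path, col_types = readr::cols())
  names(tbl)[1] <- "feature_id"
  samples <- names(tbl)[-1]
  missing <- setdiff(samples, sample_sheet$sample)
  if (length(missing)) {
    abort(sprintf("sample(s) absent from sample sheet: %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$feature_id)) abort("duplicate feature id in count table")
  for (s in samples) {
    if (!is_whole(tbl[[s]])) {
      abort(sprintf("non-integer count in sample column '%s'", s))
    }
    if (any(tbl[[s]] < 0)) abort(sprintf("negative count in column '%s'", s))
    tbl[[s]] <- as.integer(round(tbl[[s]]))
  }
  as_tibble(tbl)
}

#' Write a count table to TSV
#'
#' @param counts Tibble with `feature_id` plus sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
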