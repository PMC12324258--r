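#' Construct a genotype matrix object
#'
#' Container for additive dosage codes (0/1/2, `NA` allowed) for n
#' individuals by m markers, with per-marker allele frequencies estimated
#' from the non-missing dosages.
#'
#' @param values numeric matrix, individuals in rows, markers in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param individual_ids character vector of unique individual labels.
#' @param marker_ids character vector of unique marker labels.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `values`, `individual_ids`, `marker_ids` and `allele_freqs` (per-marker
#'   frequency of the counted allele among non-missing dosages).
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            marker_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(ncol(values)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual IDs")
  if (anyDuplicated(marker_ids)) stop("duplicate marker IDs")
  if (length(individual_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("ID lengths do not match the dosage matrix")
  ok <- values %in% c(0, 1, 2) | is.na(values)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  freqs <- colMeans(values, na.rm = TRUE) / 2
  dimnames(values) <- list(individual_ids, marker_ids)
  structure(list(values = values, individual_ids = individual_ids,
                 marker_ids = marker_ids, allele_freqs = freqs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers, %.2f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Reads SNP-major PLINK 1 binary filesets (magic bytes `0x6c 0x1b 0x01`).
#' Dosages count copies of the A1 allele; the 2-bit code `01` maps to `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  fam_tab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_tab <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_tab); m <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)  # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stop("corrupt .bed: expected ", bpm * m, " data bytes, found ",
         length(raw) - 3L)
  body <- raw[-(1:3)]
  # unpack 2-bit codes, individual 1 in the low bits of each byte
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpm, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- c(2, NA, 1, 0)
  vals <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  genotype_matrix(vals, individual_ids = as.character(fam_tab[[2]]),
                  marker_ids = as.character(bim_tab[[2]]))
}

#' Write PLINK binary genotypes (.bed/.bim/.fam)
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$values); m <- ncol(geno$values)
  fam <- data.frame(fid = geno$individual_ids, iid = geno$individual_ids,
                    pid = 0L, mid = 0L, sex = 0L, phe = -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = 1L, id = geno$marker_ids, cm = 0L,
                    pos = seq_len(m), a1 = "A", a2 = "G")
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1] <- 2L
    out[!is.na(x) & x == 0] <- 3L
    out
  }
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bpm - n
  for (j in seq_len(m)) {
    cj <- c(code_of(geno$values[, j]), integer(pad))
    dim(cj) <- c(4L, bpm)
    bytes <- cj[1, ] + 4L * cj[2, ] + 16L * cj[3, ] + 64L * cj[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
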