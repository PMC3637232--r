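# File formats: PGM images (binary P5 up to 16 bit, ASCII P2), overlay-like
# chain-code annotation files, YAML scanner-profile rosters, and the ICA
# basis archive (JSON header + raw binary matrices).

#' Write a gray image as PGM
#'
#' Binary P5 (big-endian 16-bit when `max_gray > 255`) or ASCII P2.
#'
#' @param img A `gray_image`.
#' @param path Output file path.
#' @param ascii Write ASCII P2 instead of binary P5.
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  stopifnot(inherits(img, "gray_image"))
  px <- t(img$pixels)   # PGM is row-major
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img$pixels), nrow(img$pixels)),
                 as.character(img$max_gray)), con)
    writeLines(paste(apply(img$pixels, 1, paste, collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img$pixels),
                      nrow(img$pixels), img$max_gray),
              con, eos = NULL)
    writeBin(as.integer(px), con,
             size = if (img$max_gray > 255) 2L else 1L, endian = "big")
  }
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' @param path File path.
#' @return A `gray_image`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pgm_token(con)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: magic '", magic, "'")
  w <- as.integer(read_pgm_token(con))
  h <- as.integer(read_pgm_token(con))
  maxg <- as.integer(read_pgm_token(con))
  if (magic == "P5") {
    vals <- readBin(con, "integer", n = w * h,
                    size = if (maxg > 255) 2L else 1L,
                    signed = FALSE, endian = "big")
  } else {
    vals <- integer(0)
    while (length(vals) < w * h) {
      tok <- read_pgm_token(con)
      if (!nchar(tok)) stop("truncated P2 data")
      vals <- c(vals, as.integer(tok))
    }
  }
  gray_image(matrix(vals, nrow = h, byrow = TRUE), maxg)
}

# whitespace/comment-aware token reader for PGM headers and P2 bodies
read_pgm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch)) return(paste(tok, collapse = ""))
    if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE)
                              if (!length(c2) || c2 == "\n") break } ; next }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) return(paste(tok, collapse = ""))
    } else tok <- c(tok, ch)
  }
}

#' Write chain-code annotations as an overlay-like text file
#'
#' Format: one header line `SITE <name>`, then per lesion
#' `LESION <label> START <row> <col> CHAIN <digits>` with 0-based start
#' coordinates (the in-memory representation is 1-based).
#'
#' @param annotations List of `chain_code` objects.
#' @param site Site name for the header.
#' @param path Output file path.
#' @export
write_annotations <- function(annotations, site, path) {
  lines <- c(paste("SITE", site),
             vapply(annotations, function(a)
               sprintf("LESION %s START %d %d CHAIN %s", a$label,
                       a$start[1] - 1L, a$start[2] - 1L,
                       paste(a$codes, collapse = "")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an overlay-like annotation file
#'
#' @param path File path.
#' @return List with `site` and `annotations` (list of `chain_code`).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (!grepl("^SITE ", lines[1])) stop("missing SITE header")
  site <- sub("^SITE ", "", lines[1])
  anns <- lapply(lines[-1][nzchar(lines[-1])], function(ln) {
    m <- regmatches(ln, regexec(
      "^LESION (\\S+) START (\\d+) (\\d+) CHAIN (\\d*)$", ln))[[1]]
    if (!length(m)) stop("malformed annotation line: ", ln)
    structure(list(start = c(as.integer(m[3]) + 1L, as.integer(m[4]) + 1L),
                   codes = if (nchar(m[5]))
                     as.integer(strsplit(m[5], "")[[1]]) else integer(0),
                   label = m[2]),
              class = "chain_code")
  })
  list(site = site, annotations = anns)
}

#' Write scanner profiles as a YAML roster
#'
#' @param profiles Named list of [scanner_profile()].
#' @param path Output file path.
#' @export
write_profiles <- function(profiles, path) {
  yaml::write_yaml(lapply(profiles, unclass), path)
  invisible(path)
}

#' Read a YAML scanner-profile roster
#'
#' @param path File path.
#' @return Named list of [scanner_profile()].
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p)
    scanner_profile(p$name, p$resolution_um, p$response, p$cal_a, p$cal_b,
                    p$max_gray, p$noise_sd))
}

#' Serialize an ICA basis archive
#'
#' Writes a directory containing `header.json` (dimensions, eigenvalues,
#' provenance) and raw little-endian double blobs `mean.bin`, `K_pca.bin`,
#' `W.bin`, `W_T.bin` (column-major) and `eigvals.bin`.
#'
#' @param basis An `ica_basis`.
#' @param path Directory to create.
#' @param provenance Optional list stored verbatim in the header.
#' @export
write_basis <- function(basis, path, provenance = list()) {
  stopifnot(inherits(basis, "ica_basis"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(p = basis$p, q = basis$q, eigvals = basis$eigvals,
                 provenance = provenance)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("mean", "K_pca", "W", "W_T", "eigvals")) {
    con <- file(file.path(path, paste0(nm, ".bin")), "wb")
    writeBin(as.numeric(basis[[nm]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read an ICA basis archive
#'
#' @param path Directory written by [write_basis()].
#' @return An `ica_basis`.
#' @export
read_basis <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  p <- header$p; q <- header$q
  rd <- function(nm, n) {
    con <- file(file.path(path, paste0(nm, ".bin")), "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n, size = 8, endian = "little")
  }
  build_basis(rd("mean", p),
              matrix(rd("K_pca", q * p), q, p),
              matrix(rd("W", q * q), q, q),
              rd("eigvals", q))
}

#' Write a prototype set as a flat matrix plus index
#'
#' Writes `patches_<size>.bin` (raw little-endian doubles, one row-major
#' flattened patch after another) and a tab-separated index
#' `index_<size>.tsv` with the prototype metadata.
#'
#' @param protos A `prototype_set`.
#' @param dir Output directory.
#' @export
write_prototypes <- function(protos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, sprintf("patches_%d.bin", protos$size)), "wb")
  writeBin(as.numeric(t(protos$x)), con, size = 8, endian = "little")
  close(con)
  utils::write.table(protos$meta,
                     file.path(dir, sprintf("index_%d.tsv", protos$size)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a prototype set written by [write_prototypes()]
#'
#' @param dir Directory path.
#' @param size Patch side length.
#' @return A `prototype_set`.
#' @export
read_prototypes <- function(dir, size) {
  meta <- utils::read.table(file.path(dir, sprintf("index_%d.tsv", size)),
                            sep = "\t", header = TRUE)
  n <- nrow(meta)
  con <- file(file.path(dir, sprintf("patches_%d.bin", size)), "rb")
  on.exit(close(con))
  x <- matrix(readBin(con, "numeric", n = n * size * size, size = 8,
                      endian = "little"),
              nrow = n, byrow = TRUE)
  structure(list(x = x, meta = meta, size = as.integer(size),
                 n_discarded = NA_integer_),
            class = "prototype_set")
}
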