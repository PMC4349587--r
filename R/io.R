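#' Read a STRUCTURE-format genotype file
#'
#' Reads the two-row-per-individual text layout used by STRUCTURE: each
#' individual occupies two consecutive rows (one allele per locus per row),
#' with leading label columns. A one-row layout with paired columns
#' (allele1, allele2 per locus) is also supported.
#'
#' @param path Path to the text file (whitespace-delimited).
#' @param missing Integer sentinel for missing calls (default -9, the
#'   STRUCTURE convention).
#' @param one_row Logical; if `TRUE` each individual occupies a single row
#'   with two adjacent columns per locus.
#' @param id_col,pop_col Column positions of the individual label and the
#'   population label (set `pop_col = NULL` if absent; populations then all
#'   become `"pop1"`).
#' @param loci Optional locus names (default `L1..L`).
#' @return A [genotype_matrix()].
#' @export
read_structure <- function(path, missing = -9L, one_row = FALSE,
                           id_col = 1L, pop_col = 2L, loci = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty STRUCTURE file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- vapply(toks, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("inconsistent column count (line %d has %d columns, line 1 has %d)",
                 which(ncols != ncols[1])[1], ncols[which(ncols != ncols[1])[1]], ncols[1]))
  meta_cols <- sort(c(id_col, pop_col))
  n_meta <- length(meta_cols)
  geno_cols <- setdiff(seq_len(ncols[1]), meta_cols)
  parse_int <- function(v, line_no) {
    out <- suppressWarnings(as.integer(v))
    if (any(is.na(out))) {
      bad <- v[is.na(out)][1]
      stop(sprintf("unparseable allele token '%s' at line %d", bad, line_no[is.na(out)][1]))
    }
    out
  }
  if (one_row) {
    if (length(geno_cols) %% 2L != 0L) stop("one-row layout requires an even number of genotype columns")
    L <- length(geno_cols) %/% 2L
    n <- length(toks)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    ids <- pop <- character(n)
    for (i in seq_len(n)) {
      row <- toks[[i]]
      ids[i] <- row[id_col]
      pop[i] <- if (is.null(pop_col)) "pop1" else row[pop_col]
      gv <- parse_int(row[geno_cols], rep(i, length(geno_cols)))
      a1[i, ] <- gv[seq(1L, by = 2L, length.out = L)]
      a2[i, ] <- gv[seq(2L, by = 2L, length.out = L)]
    }
  } else {
    if (length(toks) %% 2L != 0L) {
      last_id <- toks[[length(toks)]][id_col]
      stop(sprintf("two-row layout requires an even number of rows; dangling row for individual '%s'", last_id))
    }
    n <- length(toks) %/% 2L
    L <- length(geno_cols)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    ids <- pop <- character(n)
    for (i in seq_len(n)) {
      r1 <- toks[[2L * i - 1L]]
      r2 <- toks[[2L * i]]
      if (r1[id_col] != r2[id_col])
        stop(sprintf("row pair mismatch at lines %d-%d: '%s' vs '%s'",
                     2L * i - 1L, 2L * i, r1[id_col], r2[id_col]))
      ids[i] <- r1[id_col]
      pop[i] <- if (is.null(pop_col)) "pop1" else r1[pop_col]
      a1[i, ] <- parse_int(r1[geno_cols], rep(2L * i - 1L, L))
      a2[i, ] <- parse_int(r2[geno_cols], rep(2L * i, L))
    }
  }
  a1[a1 == missing] <- NA_integer_
  a2[a2 == missing] <- NA_integer_
  # a call is missing as a whole if either copy is the sentinel
  both_na <- is.na(a1) | is.na(a2)
  a1[both_na] <- NA_integer_
  a2[both_na] <- NA_integer_
  genotype_matrix(a1, a2, pop = pop, ids = ids, loci = loci)
}

#' Write a STRUCTURE-format genotype file
#'
#' Two-row-per-individual layout: columns are individual ID, population
#' label, then one allele per locus.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param missing Integer sentinel written for missing calls.
#' @export
write_structure <- function(g, path, missing = -9L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_ind(g) == 0L) stop("nothing to write: empty genotype matrix")
  enc <- function(m) {
    m[is.na(m)] <- missing
    m
  }
  a1 <- enc(g$a1); a2 <- enc(g$a2)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_ind(g))) {
    writeLines(paste(c(g$ids[i], g$pop[i], a1[i, ]), collapse = " "), con)
    writeLines(paste(c(g$ids[i], g$pop[i], a2[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a GenePop genotype file
#'
#' Supports the standard GenePop dialect: a title line, locus names (one per
#' line or comma-separated), and `Pop`-delimited blocks of
#' `id , g1 g2 ...` rows with 2- or 3-digit allele encoding per gene copy.
#' `00`/`000` decodes as missing.
#'
#' @param path Path to the GenePop file.
#' @return A [genotype_matrix()]; population labels are `pop1..popP` in
#'   file order.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GenePop file")
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1L]  # drop title
  pop_idx <- grep("^[ \t]*pop[ \t]*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'Pop' separator found")
  loc_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (!L) stop("no locus names found")
  ids <- character(0); pop <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_no <- 0L
  digits <- NA_integer_
  for (k in seq(pop_idx[1], length(body))) {
    line <- body[k]
    if (grepl("^[ \t]*pop[ \t]*$", line, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) stop(sprintf("malformed GenePop individual line: '%s'", line))
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != L)
      stop(sprintf("individual '%s' has %d genotypes but %d loci are declared", id, length(gts), L))
    w <- unique(nchar(gts))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop(sprintf("individual '%s': genotype tokens must be uniformly 4 or 6 characters", id))
    dg <- w %/% 2L
    if (is.na(digits)) digits <- dg else if (digits != dg)
      stop("mixed 2- and 3-digit allele encodings in one file")
    g1 <- as.integer(substr(gts, 1L, dg))
    g2 <- as.integer(substr(gts, dg + 1L, 2L * dg))
    if (any(is.na(g1)) || any(is.na(g2)))
      stop(sprintf("unparseable genotype token for individual '%s'", id))
    g1[g1 == 0L] <- NA_integer_
    g2[g2 == 0L] <- NA_integer_
    na <- is.na(g1) | is.na(g2)
    g1[na] <- NA_integer_; g2[na] <- NA_integer_
    ids <- c(ids, id)
    pop <- c(pop, paste0("pop", pop_no))
    rows1[[length(rows1) + 1L]] <- g1
    rows2[[length(rows2) + 1L]] <- g2
  }
  if (!length(ids)) stop("GenePop file contains no individuals")
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                  pop = pop, ids = ids, loci = loci)
}

#' Write a GenePop genotype file
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param digits Allele digit width, 2 or 3. Allele codes must fit.
#' @param title Title line.
#' @export
write_genepop <- function(g, path, digits = 3L, title = "hybridzone export") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_ind(g) == 0L) stop("nothing to write: empty genotype matrix")
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  maxcode <- suppressWarnings(max(c(g$a1, g$a2), na.rm = TRUE))
  if (is.finite(maxcode) && maxcode > 10^digits - 1L)
    stop(sprintf("allele code %d does not fit in %d digits", maxcode, digits))
  if (any(c(g$a1, g$a2) < 1L, na.rm = TRUE))
    stop("GenePop allele codes must be positive (0 is the missing code)")
  fmt <- function(v) {
    v[is.na(v)] <- 0L
    sprintf(paste0("%0", digits, "d"), v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  pops <- unique(g$pop)
  for (p in pops) {
    writeLines("Pop", con)
    for (i in which(g$pop == p)) {
      gts <- paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ]))
      writeLines(paste0(g$ids[i], " , ", paste(gts, collapse = " ")), con)
    }
  }
  invisible(path)
}
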