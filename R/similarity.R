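# Motif representations (binding-site sets, PFM, PWM, information content)
# and the SPIC-style pairwise similarity used to build motif similarity
# graphs.  The metric weights the cross-likelihood of one motif's PWM
# generating the other's column frequencies by column information content,
# averages the two directions, maximizes over ungapped offsets and both
# strands, and self-normalizes so that score(m, m) = 1.  It is a documented
# reconstruction of the published SPIC idea, not a port of the original
# binary; the clustering core treats the metric as pluggable and accepts
# precomputed edge lists via read_edge_list().

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif from aligned binding sites
#'
#' @param id motif identifier (unique within a collection).
#' @param sites character vector of equal-length sequences over ACGT
#'   (lowercase accepted and uppercased).  Sites containing other letters
#'   are dropped with a warning.
#' @return An object of class `motif` with fields `id`, `sites`, `length`,
#'   `n_sites` (and `counts = NULL`, see [motif_from_pfm()]).
#' @export
motif <- function(id, sites) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sites <- toupper(as.character(sites))
  ok <- grepl("^[ACGT]+$", sites)
  if (!all(ok)) {
    warning(sprintf("motif %s: dropped %d site(s) with non-ACGT characters",
                    id, sum(!ok)), call. = FALSE)
    sites <- sites[ok]
  }
  if (length(sites) == 0L)
    stop("motif must have at least one valid site", call. = FALSE)
  L <- unique(nchar(sites))
  if (length(L) != 1L)
    stop(sprintf("motif %s: ragged site lengths (%s)", id,
                 paste(L, collapse = ", ")), call. = FALSE)
  structure(list(id = id, sites = sites, length = L,
                 n_sites = length(sites), counts = NULL),
            class = "motif")
}

#' Construct a motif from a position frequency matrix
#'
#' For inputs where the raw sites are unavailable (JASPAR PFM files).
#'
#' @param id motif identifier.
#' @param counts 4 x L nonnegative matrix, rows A, C, G, T.
#' @return A `motif` whose `sites` is `NULL` and whose `counts` holds the
#'   PFM; `n_sites` is the (common) column sum.
#' @export
motif_from_pfm <- function(id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("PFM must be a 4 x L matrix (rows A, C, G, T)", call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("PFM counts must be nonnegative", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("PFM has an all-zero column", call. = FALSE)
  rownames(counts) <- DNA_BASES
  structure(list(id = id, sites = NULL, length = ncol(counts),
                 n_sites = max(cs), counts = counts),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif %s: L=%d, %d site(s)%s\n", x$id, x$length, x$n_sites,
              if (is.null(x$sites)) " (PFM only)" else ""))
  invisible(x)
}

#' Position frequency matrix of a motif
#'
#' `counts[b, i]` is the number of sites carrying base `b` at column `i`;
#' column sums equal the number of sites.
#'
#' @param m a `motif`.
#' @return Numeric 4 x L matrix with rows A, C, G, T.
#' @export
pfm_from_sites <- function(m) {
  stopifnot(inherits(m, "motif"))
  if (!is.null(m$counts)) return(m$counts)
  chars <- matrix(unlist(strsplit(m$sites, "", fixed = TRUE), use.names = FALSE),
                  nrow = m$n_sites, byrow = TRUE)
  counts <- vapply(seq_len(m$length), function(i)
    tabulate(factor(chars[, i], levels = DNA_BASES), nbins = 4L),
    numeric(4))
  counts <- matrix(counts, nrow = 4L, dimnames = list(DNA_BASES, NULL))
  counts
}

#' Per-column information content
#'
#' `IC = 2 + sum_b f_b log2 f_b` bits per column, with `f` the
#' pseudocount-smoothed column frequencies: 2 bits for a fully conserved
#' column, 0 for a uniform one (uniform background).
#'
#' @param pfm a 4 x L count matrix (or a `motif`).
#' @param pseudocount nonnegative count added to every cell before
#'   normalizing.
#' @return Numeric vector of length L, in bits.
#' @export
column_ic <- function(pfm, pseudocount = 0) {
  if (inherits(pfm, "motif")) pfm <- pfm_from_sites(pfm)
  stopifnot(is.numeric(pseudocount), pseudocount >= 0)
  cs <- colSums(pfm)
  if (any(cs + 4 * pseudocount == 0))
    stop("all-zero column in PFM", call. = FALSE)
  f <- sweep(pfm + pseudocount, 2, cs + 4 * pseudocount, "/")
  plogp <- ifelse(f > 0, f * log2(f), 0)
  2 + colSums(plogp)
}

#' Log-odds position weight matrix
#'
#' `log2` of pseudocount-smoothed column frequencies over the background.
#'
#' @inheritParams column_ic
#' @param background 4 base probabilities (A, C, G, T) summing to 1.  Use a
#'   strand-symmetric background (default uniform) to keep the similarity
#'   score strand-invariant.
#' @return 4 x L numeric matrix of log-odds in bits.
#' @export
motif_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.25) {
  if (inherits(pfm, "motif")) pfm <- pfm_from_sites(pfm)
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  cs <- colSums(pfm)
  f <- sweep(pfm + pseudocount, 2, cs + 4 * pseudocount, "/")
  log2(f / background)
}

#' Reverse complement of a motif
#'
#' @param m a `motif`.
#' @return A `motif` on the opposite strand (id suffixed with `_rc`).
#' @export
reverse_complement <- function(m) {
  stopifnot(inherits(m, "motif"))
  if (!is.null(m$sites)) {
    rc <- vapply(m$sites, function(s) {
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
    }, character(1), USE.NAMES = FALSE)
    motif(paste0(m$id, "_rc"), rc)
  } else {
    motif_from_pfm(paste0(m$id, "_rc"),
                   m$counts[4:1, rev(seq_len(ncol(m$counts))), drop = FALSE])
  }
}

# precomputed scoring profile: smoothed frequencies f and the IC-scaled
# log-odds matrix A, forward and reverse-complement
spic_profile <- function(m, pseudocount = 0.25, background = rep(0.25, 4)) {
  counts <- pfm_from_sites(m)
  cs <- colSums(counts)
  f <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  pwm <- log2(f / background)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + colSums(plogp)
  A <- sweep(pwm, 2, ic, "*")
  L <- ncol(f)
  list(f = f, A = A,
       f_rc = f[4:1, L:1, drop = FALSE], A_rc = A[4:1, L:1, drop = FALSE])
}

spic_selfraw <- function(p, min_overlap) {
  max(spic_raw_max(p$f, p$A, p$f, p$A, min_overlap),
      spic_raw_max(p$f, p$A, p$f_rc, p$A_rc, min_overlap))
}

#' SPIC-style similarity between two motifs
#'
#' For every ungapped offset with at least `min_overlap` aligned columns,
#' and for the second motif in both orientations, the raw score is the sum
#' over aligned column pairs `(i, j)` of
#' `0.5 * (IC1(i) * sum_b f2(b,j) pwm1(b,i) + IC2(j) * sum_b f1(b,i) pwm2(b,j))`
#' divided by `min(L1, L2)` (the per-column mean scaled by alignment
#' coverage of the shorter motif, so short chance overlaps are penalized);
#' the maximum raw score is normalized by the geometric mean of the two
#' self-similarities, clipped to `[-1, 1]` and floored at 0, so identical
#' motifs score exactly 1.  Symmetric, and invariant under
#' reverse-complementing either argument (for a strand-symmetric
#' background).
#'
#' @param m1,m2 `motif` objects.
#' @param min_overlap minimum number of aligned columns (default 4).
#' @param background 4 base probabilities (default uniform).
#' @param pseudocount smoothing count per PFM cell (default 0.25).
#' @return Similarity in `[0, 1]`.
#' @export
spic_score <- function(m1, m2, min_overlap = 4L,
                       background = rep(0.25, 4), pseudocount = 0.25) {
  stopifnot(inherits(m1, "motif"), inherits(m2, "motif"),
            is.numeric(min_overlap), min_overlap >= 1)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap > min(m1$length, m2$length))
    stop(sprintf("min_overlap (%d) exceeds the shorter motif length (%d)",
                 min_overlap, min(m1$length, m2$length)), call. = FALSE)
  p1 <- spic_profile(m1, pseudocount, background)
  p2 <- spic_profile(m2, pseudocount, background)
  raw <- max(spic_raw_max(p1$f, p1$A, p2$f, p2$A, min_overlap),
             spic_raw_max(p1$f, p1$A, p2$f_rc, p2$A_rc, min_overlap))
  s1 <- spic_selfraw(p1, min_overlap)
  s2 <- spic_selfraw(p2, min_overlap)
  if (!(s1 > 0) || !(s2 > 0)) {
    warning("non-positive self-similarity (uninformative motif); score 0",
            call. = FALSE)
    return(0)
  }
  min(max(raw / sqrt(s1 * s2), 0), 1)
}

#' All-pairs motif similarity graph
#'
#' Computes [spic_score()] for every motif pair and returns the similarity
#' graph with an edge wherever the score reaches `gamma`.  All motif ids
#' are retained as graph nodes, so motifs with no edge at the cutoff appear
#' as isolated nodes.
#'
#' @param motifs list of `motif` objects with unique ids, each at least
#'   `min_overlap` columns long.
#' @param gamma similarity cutoff in `[0, 1]`.
#' @param workers parallel workers (performance only; output identical for
#'   any value).
#' @inheritParams spic_score
#' @return A `similarity_graph` over the motif ids.
#' @export
all_pairs_similarity <- function(motifs, gamma = 0.6, workers = 1L,
                                 min_overlap = 4L,
                                 background = rep(0.25, 4),
                                 pseudocount = 0.25) {
  stopifnot(length(motifs) >= 2L)
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate motif ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lens <- vapply(motifs, `[[`, numeric(1), "length")
  min_overlap <- as.integer(min_overlap)
  if (any(lens < min_overlap))
    stop("all motifs must be at least min_overlap columns long", call. = FALSE)
  profs <- lapply(motifs, spic_profile, pseudocount = pseudocount,
                  background = background)
  fl <- lapply(profs, `[[`, "f");   Al <- lapply(profs, `[[`, "A")
  frl <- lapply(profs, `[[`, "f_rc"); Arl <- lapply(profs, `[[`, "A_rc")
  selfraw <- vapply(profs, spic_selfraw, numeric(1), min_overlap = min_overlap)
  n <- length(motifs)
  score_rows <- function(rows)
    spic_score_rows(as.integer(rows), fl, Al, frl, Arl, selfraw, min_overlap)
  workers <- as.integer(workers)
  if (workers > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, score_rows, mc.cores = workers)
    S <- do.call(rbind, parts)
  } else {
    S <- score_rows(seq_len(n))
  }
  iu <- which(upper.tri(S), arr.ind = TRUE)
  w <- S[iu]
  pass <- w >= gamma
  edges <- data.frame(from = ids[iu[pass, 1L]], to = ids[iu[pass, 2L]],
                      weight = w[pass], stringsAsFactors = FALSE)
  similarity_graph(edges, nodes = ids, gamma = gamma)
}

#' Read binding-site FASTA files (JASPAR sites format)
#'
#' Each FASTA record is one binding site; lowercase flanking letters are
#' stripped and the uppercase core is kept.
#'
#' @param path FASTA file path.
#' @param id motif id; defaults to the file name without extension.
#' @return A `motif`.
#' @export
read_sites_fasta <- function(path, id = NULL) {
  if (is.null(id))
    id <- sub("\\.(fa|fasta|sites|txt)$", "", basename(path))
  seqs <- as.character(Biostrings::readBStringSet(path))
  core <- gsub("[a-z]", "", seqs)
  core <- core[nzchar(core)]
  if (length(core) == 0L)
    stop(sprintf("no usable sites in %s", path), call. = FALSE)
  motif(id, core)
}

#' Write a motif's sites as FASTA
#'
#' @param m a `motif` with sites.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sites_fasta <- function(m, path) {
  stopifnot(inherits(m, "motif"))
  if (is.null(m$sites))
    stop("motif has no sites (PFM-only)", call. = FALSE)
  hdr <- sprintf(">%s_site%d", m$id, seq_along(m$sites))
  writeLines(as.vector(rbind(hdr, m$sites)), path)
  invisible(path)
}

#' Read JASPAR-style PFM file(s)
#'
#' Accepts the plain dialect (optional `>id` header followed by 4 rows of
#' whitespace-separated counts, rows A, C, G, T) and the bracketed JASPAR
#' dialect (`A [ 3 5 ... ]`).  A file may hold several matrices.
#'
#' @param path file path.
#' @return A list of `motif` objects (PFM-backed).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  cur_id <- NULL
  rows <- list()
  n_anon <- 0L
  flush <- function() {
    if (length(rows) == 0L) return(invisible(NULL))
    if (length(rows) != 4L)
      stop(sprintf("PFM block%s has %d rows; expected 4 (A, C, G, T)",
                   if (is.null(cur_id)) "" else paste0(" ", cur_id),
                   length(rows)), call. = FALSE)
    counts <- do.call(rbind, rows)
    id <- cur_id
    if (is.null(id)) {
      n_anon <<- n_anon + 1L
      id <- sprintf("pfm%03d", n_anon)
    }
    out[[length(out) + 1L]] <<- motif_from_pfm(id, counts)
    rows <<- list()
    cur_id <<- NULL
    invisible(NULL)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- strsplit(sub("^>\\s*", "", ln), "[ \t]+")[[1]][1]
      next
    }
    # strip a leading base letter and any brackets: "A [ 3 5 ]" or "3 5"
    body <- sub("^[ACGTacgt]\\s*", "", ln)
    body <- gsub("[][]", " ", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "[ \t]+")[[1]]))
    if (anyNA(vals))
      stop(sprintf("unparseable PFM row: %s", dQuote(ln)), call. = FALSE)
    rows[[length(rows) + 1L]] <- vals
  }
  flush()
  if (length(out) == 0L)
    stop(sprintf("no PFM records found in %s", path), call. = FALSE)
  out
}
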