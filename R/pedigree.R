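#' Pedigree objects
#'
#' A `carp_pedigree` is a data frame with columns `id`, `sire`, `dam`
#' (character; `NA` = unknown parent), stored in a topological order in which
#' every parent precedes its offspring, plus a `generation` index (founders are
#' generation 0). Animal identifiers are opaque strings; the constructor
#' computes its own ordering rather than trusting input order, so shuffled
#' files are handled correctly.
#'
#' @param id,sire,dam character vectors of equal length; use `NA` (or `""`
#'   when reading CSV) for unknown parents. Parents that appear only in the
#'   `sire`/`dam` columns are added as founders.
#' @return An object of class `carp_pedigree`.
#' @examples
#' ped <- as_pedigree(id = c("o1", "s1", "d1"),
#'                    sire = c("s1", NA, NA), dam = c("d1", NA, NA))
#' ped$generation
#' @export
as_pedigree <- function(id, sire = NULL, dam = NULL) {
  if (is.data.frame(id)) {
    df <- id
    stopifnot(all(c("id", "sire", "dam") %in% names(df)))
    id <- as.character(df$id); sire <- as.character(df$sire); dam <- as.character(df$dam)
  }
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[!is.na(sire) & sire == ""] <- NA
  dam[!is.na(dam) & dam == ""] <- NA
  if (anyDuplicated(id)) stop("duplicated animal ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  # implicit founders: parents never listed as animals
  extra <- setdiff(c(sire, dam), c(id, NA))
  if (length(extra)) {
    id <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  # Kahn-style topological ordering with generation numbers; detects cycles.
  gen <- rep(NA_integer_, n)
  gen[is.na(si) & is.na(di)] <- 0L
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    ready <- todo[vapply(todo, function(i)
      (is.na(si[i]) || !is.na(gen[si[i]])) &&
      (is.na(di[i]) || !is.na(gen[di[i]])), logical(1))]
    if (!length(ready)) stop("pedigree contains a cycle involving: ",
                             paste(id[todo], collapse = ", "))
    for (i in ready) {
      gen[i] <- 1L + max(gen[si[i]], gen[di[i]], -1L, na.rm = TRUE)
    }
  }
  ord <- order(gen, seq_along(id))
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    generation = gen[ord], stringsAsFactors = FALSE)
  class(out) <- c("carp_pedigree", "data.frame")
  out
}

#' @export
print.carp_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree:", nrow(x), "animals (", founders, "founders,",
      nrow(x) - founders, "non-founders ),",
      max(x$generation) + 1L, "generation(s)\n")
  if (!is.null(attr(x, "crosses")))
    cat("Mating design:", nrow(attr(x, "crosses")), "admissible sire x dam crosses\n")
  invisible(x)
}

#' Read / write pedigree CSV
#'
#' CSV contract: columns `id,sire,dam`; an empty field means unknown parent.
#'
#' @param file path to a CSV file.
#' @return [read_pedigree()] returns a `carp_pedigree`.
#' @export
read_pedigree <- function(file) {
  df <- read.csv(file, colClasses = "character")
  as_pedigree(df)
}

#' @param ped a `carp_pedigree`.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  df <- as.data.frame(ped)[, c("id", "sire", "dam")]
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Partial factorial mating design
#'
#' Builds the founder layer of a partial factorial design: `n_series`
#' independent series, each a full factorial of `dams_per_series` dams by
#' `sires_per_series` sires; no crosses across series. This is the classic
#' design used to create overlapping full- and half-sib families in fish
#' breeding experiments (e.g. 4 series of 5 dams x 10 sires giving 60 founders
#' and 200 admissible full-sib families).
#'
#' @param n_series,dams_per_series,sires_per_series positive integer counts.
#' @return A `carp_pedigree` of founders with attribute `"crosses"`, a data
#'   frame of admissible matings (`sire`, `dam`, `series`).
#' @examples
#' ped <- build_partial_factorial(4, 5, 10)
#' nrow(ped)                    # 60 founders
#' nrow(attr(ped, "crosses"))   # 200 admissible crosses
#' @export
build_partial_factorial <- function(n_series, dams_per_series, sires_per_series) {
  stopifnot(n_series >= 1, dams_per_series >= 1, sires_per_series >= 1)
  dams <- sprintf("D%02d", seq_len(n_series * dams_per_series))
  sires <- sprintf("S%02d", seq_len(n_series * sires_per_series))
  ped <- as_pedigree(id = c(dams, sires))
  crosses <- do.call(rbind, lapply(seq_len(n_series), function(s) {
    d <- dams[(s - 1) * dams_per_series + seq_len(dams_per_series)]
    si <- sires[(s - 1) * sires_per_series + seq_len(sires_per_series)]
    expand.grid(sire = si, dam = d, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)[, c("sire", "dam")] |>
      cbind(series = s)
  }))
  rownames(crosses) <- NULL
  attr(ped, "crosses") <- crosses
  ped
}

#' Numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A over a pedigree by
#' the tabular method, or its inverse built directly from Henderson's
#' contribution rules (with Quaas' correction for inbred parents), never by
#' numeric inversion.
#'
#' The tabular recursion: processing animals in an order where parents precede
#' offspring, `a_ij = (a_{s(i)j} + a_{d(i)j})/2` for j preceding i and
#' `a_ii = 1 + a_{s(i)d(i)}/2` (missing parents contribute 0). The inverse is
#' assembled per animal with `delta = 1/(0.5 - 0.25 (F_s + F_d))` (both
#' parents known; analogous rules with one or no known parent), adding `delta`
#' to (i,i), `-delta/2` to (i,parent) and `delta/4` to the parent block.
#'
#' @param ped a [carp_pedigree][as_pedigree].
#' @param inverse logical; return `A^-1` instead of A.
#' @return A dense symmetric matrix with dimnames = animal ids (in pedigree
#'   order).
#' @examples
#' ped <- as_pedigree(id = c("s", "d", "o1", "o2"),
#'                    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
#' A <- relationship_matrix(ped)
#' A["o1", "o2"]  # full sibs: 0.5
#' @export
relationship_matrix <- function(ped, inverse = FALSE) {
  stopifnot(inherits(ped, "carp_pedigree"))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    stop("offspring listed before a parent; rebuild the pedigree with as_pedigree()")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[j, s]
      if (!is.na(d)) row <- row + A[j, d]
      A[j, i] <- A[i, j] <- row / 2
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  if (!inverse) return(A)
  f <- diag(A) - 1  # inbreeding coefficients from the tabular pass
  Ainv <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    known <- c(s, d)[!is.na(c(s, d))]
    delta <- 1 / switch(as.character(length(known)),
                        "0" = 1,
                        "1" = 0.75 - 0.25 * f[known],
                        "2" = 0.5 - 0.25 * (f[s] + f[d]))
    Ainv[i, i] <- Ainv[i, i] + delta
    for (p in known) {
      Ainv[i, p] <- Ainv[i, p] - delta / 2
      Ainv[p, i] <- Ainv[p, i] - delta / 2
    }
    for (p in known) for (q in known)
      Ainv[p, q] <- Ainv[p, q] + delta / 4
  }
  Ainv
}

#' Export a symmetric matrix as coordinate triplets
#'
#' Writes the non-zero upper triangle (including the diagonal) of a symmetric
#' matrix as `row,col,value` text for inspection, using the matrix dimnames as
#' labels.
#'
#' @param m symmetric matrix with dimnames.
#' @param file output path.
#' @export
write_matrix_triplets <- function(m, file) {
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(row = rownames(m)[idx[, 1]], col = colnames(m)[idx[, 2]],
                   value = m[idx])
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Progeny bookkeeping per sire, dam and full-sib family
#'
#' @param ped a [carp_pedigree][as_pedigree].
#' @param phenotyped_ids character vector of animals with phenotypes (subset of
#'   `ped$id`).
#' @return A list with per-sire and per-dam count summaries (min/mean/max and
#'   the rounded mean), the number of realized full-sib families, and the raw
#'   per-family count table.
#' @examples
#' ped <- as_pedigree(id = c("s", "d", "o1", "o2"),
#'                    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
#' family_summary(ped, c("o1", "o2"))$n_families
#' @export
family_summary <- function(ped, phenotyped_ids) {
  stopifnot(inherits(ped, "carp_pedigree"))
  phenotyped_ids <- as.character(phenotyped_ids)
  if (!all(phenotyped_ids %in% ped$id))
    stop("phenotyped ids not in pedigree: ",
         paste(head(setdiff(phenotyped_ids, ped$id)), collapse = ", "))
  keep <- ped[ped$id %in% phenotyped_ids & !(is.na(ped$sire) & is.na(ped$dam)), ]
  count_by <- function(key) {
    if (!nrow(keep)) return(list(min = 0, mean = 0, mean_rounded = 0, max = 0))
    tab <- table(keep[[key]])
    list(min = min(tab), mean = mean(tab), mean_rounded = round(mean(tab)),
         max = max(tab))
  }
  fam <- if (nrow(keep)) table(paste(keep$sire, keep$dam, sep = " x ")) else table(character())
  list(per_sire = count_by("sire"),
       per_dam = count_by("dam"),
       n_families = length(fam),
       family_counts = fam)
}
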