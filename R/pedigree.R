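#' Build a pedigree object
#'
#' Takes identifiers of each individual with its sire and dam (`0`, `""` or
#' `NA` meaning unknown) and an optional founder population label, orders the
#' individuals topologically so parents precede offspring, and computes
#' inbreeding coefficients by the Meuwissen-Luo algorithm.  Unknown parents
#' are treated as unrelated, non-inbred founders of the declared population.
#'
#' @param id,sire,dam vectors of identifiers (coerced to character).
#' @param population optional character vector of founder population labels.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- pedigree(id = c("s", "d", "o"), sire = c(0, 0, "s"), dam = c(0, 0, "d"))
#' ped
#' @export
pedigree <- function(id, sire, dam, population = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicated individual ids in pedigree")
  miss <- function(x) is.na(x) | x %in% c("0", "")
  sire[miss(sire)] <- NA_character_
  dam[miss(dam)] <- NA_character_
  unknown <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(unknown))
    stop("parents not listed as individuals: ", paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(population)) population <- rep(NA_character_, n)
  population <- as.character(population)
  population[population %in% c("", "0")] <- NA_character_

  # topological order (Kahn); a leftover individual implies a cycle
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (pr in c(si[i], di[i])) {
      if (!is.na(pr)) {
        indeg[i] <- indeg[i] + 1L
        children[[pr]] <- c(children[[pr]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != n)
    stop("cyclic pedigree: an individual is its own ancestor")

  id <- id[order]; si <- si[order]; di <- di[order]
  population <- population[order]
  pos <- match(seq_len(n), order)          # old index -> new position
  sire_i <- ifelse(is.na(si), 0L, pos[si])
  dam_i <- ifelse(is.na(di), 0L, pos[di])

  f <- .inbreeding_ml(as.integer(sire_i), as.integer(dam_i))
  new("Pedigree", id = id, sire = as.integer(sire_i), dam = as.integer(dam_i),
      population = population, f = f)
}

# Meuwissen-Luo inbreeding: A_ii = sum_j v_j^2 d_j over ancestors j, where
# d_j is the Mendelian sampling variance 1 - 0.25(1+F_s) - 0.25(1+F_d)
# (terms dropped for unknown parents).
.inbreeding_ml <- function(sire, dam) {
  n <- length(sire)
  f <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    d[i] <- 1 -
      (if (s > 0L) 0.25 * (1 + f[s]) else 0) -
      (if (dd > 0L) 0.25 * (1 + f[dd]) else 0)
    if (s == 0L || dd == 0L) { f[i] <- 0; next }
    v <- numeric(i)
    v[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (v[j] == 0) next
      aii <- aii + v[j]^2 * d[j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0L) v[sj] <- v[sj] + 0.5 * v[j]
      if (dj > 0L) v[dj] <- v[dj] + 0.5 * v[j]
    }
    f[i] <- aii - 1
  }
  f
}

#' @describeIn pedigree number of individuals
#' @param ped a [Pedigree-class]
#' @export
nIndividuals <- function(ped) length(ped@id)

#' @describeIn pedigree inbreeding coefficients (Meuwissen-Luo)
#' @export
inbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  setNames(ped@f, ped@id)
}

#' Read / write pedigree files
#'
#' Delimited text (comma or tab, autodetected) with header columns
#' `id`, `sire`, `dam` and optionally `population`; `0` or empty means
#' unknown parent.
#'
#' @param path file path.
#' @return `readPedigree`: a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  tab <- .read_delim(path)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(tab)))
    stop("pedigree file must have columns id, sire, dam (got: ",
         paste(names(tab), collapse = ", "), ")")
  pedigree(tab$id, tab$sire, tab$dam,
           population = if ("population" %in% names(tab)) tab$population else NULL)
}

#' @rdname readPedigree
#' @param ped a [Pedigree-class]
#' @param sep field separator.
#' @export
writePedigree <- function(ped, path, sep = "\t") {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  sire_id <- rep("0", n); dam_id <- rep("0", n)
  sire_id[ped@sire > 0L] <- ped@id[ped@sire[ped@sire > 0L]]
  dam_id[ped@dam > 0L] <- ped@id[ped@dam[ped@dam > 0L]]
  tab <- data.frame(
    id = ped@id, sire = sire_id, dam = dam_id,
    population = ifelse(is.na(ped@population), "", ped@population))
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_delim <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", strip.white = TRUE)
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix `A` by the tabular
#' method and its sparse inverse directly by Henderson's rules, both
#' accounting for inbreeding.  For large pedigrees the dense `A` can be
#' skipped (`keepA = FALSE`); model fitting only needs the sparse inverse.
#'
#' @param ped a [Pedigree-class].
#' @param keepA materialise the dense `A`? Defaults to `TRUE` for pedigrees
#'   of at most 2000 individuals.
#' @return a [RelationshipMatrix-class].
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(0, 0, "s"), c(0, 0, "d"))
#' rel <- buildRelationship(ped)
#' rel@A["o", "s"]   # parent-offspring relationship: 0.5
#' @export
buildRelationship <- function(ped, keepA = nIndividuals(ped) <= 2000) {
  stopifnot(is(ped, "Pedigree"))
  n <- nIndividuals(ped)
  sire <- ped@sire; dam <- ped@dam; f <- ped@f

  A <- NULL
  if (keepA) {
    A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
    for (i in seq_len(n)) {
      s <- sire[i]; d <- dam[i]
      if (i > 1) {
        js <- seq_len(i - 1L)
        aij <- numeric(i - 1L)
        if (s > 0L) aij <- aij + 0.5 * A[s, js]
        if (d > 0L) aij <- aij + 0.5 * A[d, js]
        A[i, js] <- aij
        A[js, i] <- aij
      }
      A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
    }
  }

  # Henderson's rules: contributions 1/d_i from each individual's Mendelian
  # sampling variance d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d).
  dvec <- 1 -
    ifelse(sire > 0L, 0.25 * (1 + f[pmax(sire, 1L)]), 0) -
    ifelse(dam > 0L, 0.25 * (1 + f[pmax(dam, 1L)]), 0)
  w <- 1 / dvec
  idx <- seq_len(n)
  ii <- idx; jj <- idx; xx <- w
  hs <- sire > 0L; hd <- dam > 0L
  ii <- c(ii, idx[hs], sire[hs]); jj <- c(jj, sire[hs], idx[hs])
  xx <- c(xx, rep(-w[hs] / 2, 2))
  ii <- c(ii, idx[hd], dam[hd]); jj <- c(jj, dam[hd], idx[hd])
  xx <- c(xx, rep(-w[hd] / 2, 2))
  ii <- c(ii, sire[hs]); jj <- c(jj, sire[hs]); xx <- c(xx, w[hs] / 4)
  ii <- c(ii, dam[hd]); jj <- c(jj, dam[hd]); xx <- c(xx, w[hd] / 4)
  both <- hs & hd
  ii <- c(ii, sire[both], dam[both]); jj <- c(jj, dam[both], sire[both])
  xx <- c(xx, rep(w[both] / 4, 2))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  new("RelationshipMatrix", A = A, Ainv = Ainv, f = f)
}
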