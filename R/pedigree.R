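#' Pedigree container
#'
#' Validated acyclic pedigree.  Parents must be recorded both-or-none (an
#' individual with exactly one known parent is rejected: gene dropping and
#' IBD enumeration need either two transmitting parents or a founder).
#'
#' @param id Character vector of individual ids.
#' @param sire,dam Parent ids (\code{NA} or \code{"0"} = unknown/founder).
#' @param sex Optional sex labels ("male"/"female"/NA), recycled if length 1.
#' @return An object of class \code{pedigree} with a topological \code{depth}
#'   (founders 0, children strictly deeper than their parents).
#' @export
pedigree <- function(id, sire, dam, sex = NA_character_) {
  id <- as.character(id)
  sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% c("0", "")] <- NA; dam[dam %in% c("0", "")] <- NA
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  if (any(xor(is.na(sire), is.na(dam)))) {
    stop("individuals must have both parents recorded, or neither")
  }
  known <- stats::na.omit(c(sire, dam))
  if (length(bad <- setdiff(known, id))) {
    stop("parent ids not present in pedigree: ", paste(bad, collapse = ", "))
  }
  n <- length(id)
  members <- data.frame(id = id, sire = sire, dam = dam,
                        sex = rep_len(as.character(sex), n),
                        stringsAsFactors = FALSE)
  # Kahn topological order; leftover nodes imply a cycle
  depth <- stats::setNames(rep(NA_real_, n), id)
  depth[is.na(sire)] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!is.na(depth[id[i]]) || is.na(sire[i])) next
      ds <- depth[sire[i]]; dd <- depth[dam[i]]
      if (!is.na(ds) && !is.na(dd)) {
        depth[id[i]] <- max(ds, dd) + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(depth)) {
    stop("pedigree contains a cycle involving: ",
         paste(id[is.na(depth[id])], collapse = ", "))
  }
  structure(list(members = members, depth = depth), class = "pedigree")
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members, %d founders, max depth %d\n",
              nrow(x$members), sum(is.na(x$members$sire)),
              as.integer(max(x$depth))))
  invisible(x)
}

ped_parents <- function(ped, a) {
  i <- match(a, ped$members$id)
  if (is.na(i)) stop("unknown pedigree id: ", a)
  c(ped$members$sire[i], ped$members$dam[i])
}

#' Exact pedigree kinship coefficient
#'
#' Recursive kinship: phi(a,a) = (1 + phi(sire_a, dam_a)) / 2 and
#' phi(a,b) = (phi(sire_a, b) + phi(dam_a, b)) / 2, expanding the deeper
#' individual first.  Founders are taken unrelated and non-inbred.
#' Memoized; exact rational arithmetic is not needed because every value is
#' a dyadic fraction representable in double precision.
#'
#' @param ped A \code{\link{pedigree}}.
#' @param a,b Individual ids.
#' @return Kinship coefficient (0.25 parent-offspring, 0.125
#'   grandparent-grandchild, ...).
#' @export
pedigree_phi <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"))
  if (length(bad <- setdiff(c(a, b), ped$members$id))) {
    stop("unknown pedigree id: ", paste(bad, collapse = ", "))
  }
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(v <- memo[[key]])) return(v)
    pa <- ped_parents(ped, a)
    val <- if (a == b) {
      (1 + phi(pa[1L], pa[2L])) / 2
    } else {
      # expand the deeper individual; a founder pair is unrelated
      if (ped$depth[b] > ped$depth[a]) { tmp <- a; a <- b; b <- tmp }
      pa <- ped_parents(ped, a)
      if (all(is.na(pa))) 0 else (phi(pa[1L], b) + phi(pa[2L], b)) / 2
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

# ids of a, b and all their ancestors, in topological order
ped_restrict <- function(ped, a, b) {
  need <- character(0)
  stack <- c(a, b)
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    if (x %in% need || is.na(x)) next
    need <- c(need, x)
    stack <- c(stack, ped_parents(ped, x))
  }
  need[order(ped$depth[need])]
}

#' Exact IBD-sharing probabilities for a non-inbred pair
#'
#' Enumerates every inheritance vector (one bit per parent-child
#' transmission, uniform) on the pedigree restricted to the ancestors of the
#' pair, labels founder alleles uniquely, and tabulates how many alleles the
#' pair shares identical by descent.  Feasible up to
#' \code{max_transmissions} bits; larger pedigrees must use the seeded Monte
#' Carlo fallback (\code{method = "monte_carlo"}).
#'
#' @param ped A \code{\link{pedigree}}.
#' @param a,b Individual ids (pair must be non-inbred).
#' @param method "exact" enumeration or "monte_carlo".
#' @param n_draws Monte Carlo draws.
#' @param seed Seed for the Monte Carlo fallback.
#' @param max_transmissions Enumeration limit (2 bits per non-founder).
#' @return Numeric \code{c(delta0, delta1, delta2)}.
#' @export
pedigree_deltas <- function(ped, a, b, method = c("exact", "monte_carlo"),
                            n_draws = 1e6, seed = 1L,
                            max_transmissions = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "pedigree"))
  for (x in c(a, b)) {
    pa <- ped_parents(ped, x)
    if (!all(is.na(pa)) && pedigree_phi(ped, pa[1L], pa[2L]) > 0) {
      stop("pair is inbred; condensed identity coefficients are out of scope")
    }
  }
  ids <- ped_restrict(ped, a, b)
  sub <- ped$members[match(ids, ped$members$id), ]
  nonf <- sub$id[!is.na(sub$sire)]
  n_trans <- 2L * length(nonf)
  if (method == "exact") {
    if (n_trans > max_transmissions) {
      stop(sprintf(paste0("pedigree needs %d transmission bits ",
                          "(limit %d); use method = \"monte_carlo\""),
                   n_trans, max_transmissions))
    }
    nv <- 2L^n_trans
    bits <- matrix(0L, nrow = max(nv, 1L), ncol = max(n_trans, 1L))
    if (n_trans > 0L) {
      for (t in seq_len(n_trans)) {
        bits[, t] <- rep(rep(0:1, each = 2L^(t - 1L)), length.out = nv)
      }
    }
    deltas_from_bits(sub, nonf, bits, a, b)
  } else {
    bits <- with_seed(seed, {
      matrix(sample(0:1, n_draws * max(n_trans, 1L), replace = TRUE),
             nrow = n_draws)
    })
    deltas_from_bits(sub, nonf, bits, a, b)
  }
}

# shared worker: rows of `bits` are inheritance vectors (2 bits per
# non-founder: sire-side choice, dam-side choice)
deltas_from_bits <- function(sub, nonf, bits, a, b) {
  nv <- nrow(bits)
  al1 <- list(); al2 <- list()   # per id: vectors of founder-allele labels
  lab <- 0L
  for (i in seq_len(nrow(sub))) {
    id <- sub$id[i]
    if (is.na(sub$sire[i])) {
      al1[[id]] <- rep.int(lab + 1L, nv)
      al2[[id]] <- rep.int(lab + 2L, nv)
      lab <- lab + 2L
    } else {
      t0 <- 2L * (match(id, nonf) - 1L)
      s <- sub$sire[i]; d <- sub$dam[i]
      al1[[id]] <- ifelse(bits[, t0 + 1L] == 0L, al1[[s]], al2[[s]])
      al2[[id]] <- ifelse(bits[, t0 + 2L] == 0L, al1[[d]], al2[[d]])
    }
  }
  # non-inbred pair: each individual's two alleles are distinct labels,
  # so IBD count = size of the label intersection
  shared <- (al1[[a]] == al1[[b]]) + (al1[[a]] == al2[[b]]) +
            (al2[[a]] == al1[[b]]) + (al2[[a]] == al2[[b]])
  c(delta0 = mean(shared == 0L),
    delta1 = mean(shared == 1L),
    delta2 = mean(shared == 2L))
}

#' Pedigree-expected kinship table for a list of pairs
#'
#' Applies \code{\link{pedigree_phi}} and \code{\link{pedigree_deltas}} per
#' pair and bands the relationship degree as
#' \code{round(-log2(2 * phi))} (1 = parent-offspring/full sib,
#' 2 = grandparent/half-sib/avuncular, ...), or \code{"unrelated"} for
#' phi = 0.
#'
#' @param ped A \code{\link{pedigree}}.
#' @param pairs Two-column matrix or data frame of id pairs.
#' @param deltas Whether to include exact IBD-state probabilities.
#' @return Data frame with columns id1, id2, phi_exp, delta0..2, degree.
#' @export
expected_table <- function(ped, pairs, deltas = TRUE) {
  pairs <- as.matrix(pairs)
  out <- data.frame(id1 = pairs[, 1L], id2 = pairs[, 2L],
                    phi_exp = NA_real_, delta0 = NA_real_,
                    delta1 = NA_real_, delta2 = NA_real_,
                    degree = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    phi <- pedigree_phi(ped, out$id1[i], out$id2[i])
    out$phi_exp[i] <- phi
    if (deltas) {
      d <- pedigree_deltas(ped, out$id1[i], out$id2[i])
      out[i, c("delta0", "delta1", "delta2")] <- as.list(unname(d))
    }
    out$degree[i] <- if (phi > 0) {
      as.character(round(-log2(2 * phi)))
    } else "unrelated"
  }
  out
}
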