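#' Pedigree of a recombinant inbred line
#'
#' A `cc_pedigree` holds one line's ancestry table: one row per animal with
#' columns `id`, `sire`, `dam`, `sex` ("male"/"female"), `generation`
#' (integer, 0 for the funnel founders) and `line`.  Founders are exactly
#' the animals with no recorded parents; for an eight-way funnel there are
#' eight of them.  The parent relation must be acyclic, every referenced
#' parent must be present, sires must be male and dams female.
#'
#' @param df data.frame with the six columns above.  Missing parents are
#'   `NA` or the empty string.
#' @return an object of class `cc_pedigree`.
#' @export
cc_pedigree <- function(df) {
  need <- c("id", "sire", "dam", "sex", "generation", "line")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("pedigree table lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (col in c("id", "sire", "dam", "sex", "line"))
    df[[col]] <- as.character(df[[col]])
  df$sire[!nzchar(df$sire) | is.na(df$sire)] <- NA_character_
  df$dam[!nzchar(df$dam) | is.na(df$dam)] <- NA_character_
  df$generation <- as.integer(df$generation)

  if (anyDuplicated(df$id))
    stop("duplicated animal id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(is.na(df$generation) | df$generation < 0L))
    stop("generation must be a non-negative integer")
  one_parent <- xor(is.na(df$sire), is.na(df$dam))
  if (any(one_parent))
    stop("animal(s) with exactly one recorded parent: ",
         paste(df$id[one_parent], collapse = ", "))

  for (col in c("sire", "dam")) {
    ref <- df[[col]][!is.na(df[[col]])]
    unknown <- setdiff(ref, df$id)
    if (length(unknown) > 0L)
      stop("missing ", col, " id(s): ", paste(unknown, collapse = ", "))
  }
  sire_sex <- df$sex[match(df$sire, df$id)]
  bad <- !is.na(df$sire) & sire_sex != "male"
  if (any(bad))
    stop("sire is not male for: ",
         paste(unique(df$sire[bad]), collapse = ", "))
  dam_sex <- df$sex[match(df$dam, df$id)]
  bad <- !is.na(df$dam) & dam_sex != "female"
  if (any(bad))
    stop("dam is not female for: ",
         paste(unique(df$dam[bad]), collapse = ", "))

  # cycle check: peel animals whose parents are already peeled
  remaining <- df$id
  known <- character(0)
  repeat {
    ok <- is.na(df$sire[match(remaining, df$id)]) |
      (df$sire[match(remaining, df$id)] %in% known &
         df$dam[match(remaining, df$id)] %in% known)
    if (!any(ok)) break
    known <- c(known, remaining[ok])
    remaining <- remaining[!ok]
    if (length(remaining) == 0L) break
  }
  if (length(remaining) > 0L)
    stop("cycle detected in pedigree involving: ",
         paste(remaining, collapse = " -> "))

  structure(list(tab = df,
                 line_id = paste(sort(unique(df$line)), collapse = "+")),
            class = "cc_pedigree")
}

#' @export
print.cc_pedigree <- function(x, ...) {
  cat("<cc_pedigree> line", x$line_id, "-", nrow(x$tab), "animals,",
      length(pedigree_founders(x)), "founders, max generation",
      max(x$tab$generation), "\n")
  invisible(x)
}

#' Founders of a pedigree
#'
#' @param p a [cc_pedigree()].
#' @return character vector of ids of the parentless animals.
#' @export
pedigree_founders <- function(p) {
  p$tab$id[is.na(p$tab$sire)]
}

#' Read / write a pedigree CSV
#'
#' The on-disk dialect is CSV with header
#' `id,sire,dam,sex,generation,line`; an empty string means no parent.
#'
#' @param path file path.
#' @return `read_pedigree` returns a validated [cc_pedigree()];
#'   `write_pedigree` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  cc_pedigree(df)
}

#' @rdname read_pedigree
#' @param p a [cc_pedigree()].
#' @export
write_pedigree <- function(p, path) {
  tab <- p$tab
  tab$sire[is.na(tab$sire)] <- ""
  tab$dam[is.na(tab$dam)] <- ""
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_ids <- function(p, ids) {
  unknown <- setdiff(ids, p$tab$id)
  if (length(unknown) > 0L)
    stop("unknown animal id(s): ", paste(unknown, collapse = ", "))
}

children_map <- function(p) {
  tab <- p$tab
  edges <- rbind(
    data.frame(parent = tab$sire, child = tab$id, stringsAsFactors = FALSE),
    data.frame(parent = tab$dam, child = tab$id, stringsAsFactors = FALSE))
  edges <- edges[!is.na(edges$parent), , drop = FALSE]
  split(edges$child, factor(edges$parent, levels = tab$id))
}

#' All descendants of a set of animals
#'
#' @param p a [cc_pedigree()].
#' @param ids character vector of animal ids.
#' @return character vector of all animals reachable from `ids` through
#'   parent-to-child edges, excluding `ids` themselves.
#' @export
descendants <- function(p, ids) {
  check_ids(p, ids)
  kids <- children_map(p)
  seen <- character(0)
  frontier <- unique(ids)
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, ids))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

ancestors_of <- function(p, id) {
  tab <- p$tab
  seen <- character(0)
  frontier <- id
  while (length(frontier) > 0L) {
    i <- match(frontier, tab$id)
    nxt <- unique(c(tab$sire[i], tab$dam[i]))
    nxt <- setdiff(nxt[!is.na(nxt)], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' All recorded matings of a pedigree
#'
#' @param p a [cc_pedigree()].
#' @return data.frame `sire`, `dam`, `generation` (max of the pair's own
#'   generations), one row per distinct pair with at least one offspring.
#' @export
matings <- function(p) {
  tab <- p$tab
  has_par <- !is.na(tab$sire)
  pairs <- unique(tab[has_par, c("sire", "dam")])
  gen <- pmax(tab$generation[match(pairs$sire, tab$id)],
              tab$generation[match(pairs$dam, tab$id)])
  out <- data.frame(sire = pairs$sire, dam = pairs$dam, generation = gen,
                    stringsAsFactors = FALSE)
  out <- out[order(out$generation, out$sire, out$dam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Obligate ancestor pairs of a set of extant animals
#'
#' A mating pair (sire, dam) is an obligate ancestor pair of `extant` when
#' (i) every extant animal descends from both members and (ii) every
#' ancestry path from any extant animal back to the funnel founders passes
#' through one of the pair's offspring -- equivalently, removing the pair's
#' offspring disconnects `extant` from the founders.  The pair's four
#' haplotypes therefore bound everything that can still segregate among the
#' extant animals.  Funnel founders are never reported as obligate
#' ancestors: they are ancestors of everything by construction and carry no
#' information about residual heterozygosity.
#'
#' @param p a [cc_pedigree()].
#' @param extant nonempty character vector of animal ids, all in one line.
#' @return data.frame `sire`, `dam`, `generation`, ordered by generation
#'   ascending (ties by sire then dam id).  May have zero rows.
#' @export
obligate_ancestor_pairs <- function(p, extant) {
  if (length(extant) == 0L) stop("extant set is empty")
  extant <- unique(extant)
  check_ids(p, extant)
  lines <- unique(p$tab$line[match(extant, p$tab$id)])
  if (length(lines) > 1L)
    stop("extant animals belong to different lines: ",
         paste(lines, collapse = ", "))

  tab <- p$tab
  founder_ids <- pedigree_founders(p)
  anc <- lapply(extant, function(e) ancestors_of(p, e))
  cand <- matings(p)
  is_founder_pair <- cand$sire %in% founder_ids | cand$dam %in% founder_ids
  cand <- cand[!is_founder_pair, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)

  ok <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$sire[i]; d <- cand$dam[i]
    below <- all(vapply(seq_along(extant), function(j) {
      s %in% anc[[j]] && d %in% anc[[j]]
    }, logical(1)))
    if (!below) next
    offspring <- tab$id[!is.na(tab$sire) & tab$sire == s & tab$dam == d]
    # upward search from extant, blocked at the pair's offspring
    frontier <- setdiff(extant, offspring)
    seen <- frontier
    reached_founder <- any(frontier %in% founder_ids)
    while (!reached_founder && length(frontier) > 0L) {
      k <- match(frontier, tab$id)
      nxt <- unique(c(tab$sire[k], tab$dam[k]))
      nxt <- setdiff(nxt[!is.na(nxt)], c(seen, offspring))
      if (any(nxt %in% founder_ids)) reached_founder <- TRUE
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    ok[i] <- !reached_founder
  }
  out <- cand[ok, , drop = FALSE]
  out <- out[order(out$generation, out$sire, out$dam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most recent obligate ancestor pair
#'
#' The obligate pair of maximal generation; this is the pair whose genomes
#' are jointly examined to bound the line's residual heterozygosity.  Ties
#' on generation are broken toward the lexicographically smallest
#' (sire, dam) and reported with a warning.
#'
#' @inheritParams obligate_ancestor_pairs
#' @return one-row data.frame `sire`, `dam`, `generation`.
#' @export
most_recent_obligate_ancestors <- function(p, extant) {
  pairs <- obligate_ancestor_pairs(p, extant)
  if (nrow(pairs) == 0L)
    stop("no obligate ancestor pair exists for the given extant set ",
         "(does it include a funnel founder?)")
  top <- pairs[pairs$generation == max(pairs$generation), , drop = FALSE]
  if (nrow(top) > 1L) {
    top <- top[order(top$sire, top$dam), , drop = FALSE]
    warning("generation tie among obligate pairs; choosing (",
            top$sire[1], ", ", top$dam[1], ")")
  }
  rownames(top) <- NULL
  top[1, , drop = FALSE]
}
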