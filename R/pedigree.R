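#' Construct a validated pedigree
#'
#' A pedigree is a data frame with one row per individual, topologically
#' sorted so that parents always precede their offspring. Founders (both
#' parents unknown) are assumed unrelated and non-inbred.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam identifiers of the parents; `NA` (or any code listed in
#'   `unknown`) marks an unknown parent.
#' @param sex optional sex codes; `"M"`/`"F"` (also accepted: `male`/`female`,
#'   `1`/`2`). Missing sexes are inferred from parental roles where possible.
#' @param birth optional numeric birth time: calendar year for real
#'   studbooks, generation index for simulated pedigrees.
#' @param flock optional location / herd label.
#' @param ... passed to [as_pedigree()].
#' @return An object of class `pedigree` (a data frame with columns `id`,
#'   `sire`, `dam`, `sex`, `birth`, `flock`), topologically sorted.
#' @examples
#' ped <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
#'                 dam = c(NA, NA, "B"), sex = c("M", "F", "M"))
#' inbreeding(ped)
#' @export
pedigree <- function(id, sire, dam, sex = NULL, birth = NULL, flock = NULL,
                     ...) {
  n <- length(id)
  df <- data.frame(id = as.character(id), sire = as.character(sire),
                   dam = as.character(dam),
                   sex = if (is.null(sex)) rep(NA_character_, n) else as.character(sex),
                   birth = if (is.null(birth)) rep(NA_real_, n) else as.numeric(birth),
                   flock = if (is.null(flock)) rep(NA_character_, n) else as.character(flock),
                   stringsAsFactors = FALSE)
  as_pedigree(df, ...)
}

#' Coerce a data frame to a validated pedigree
#'
#' Validates identifiers, parent links and sexes, resolves unknown-parent
#' codes, and topologically sorts the rows (parents before offspring).
#' Cycles (an individual that is its own ancestor), duplicated ids and ids
#' used both as sire and dam are hard errors.
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `birth`, `flock`.
#' @param unknown character codes (besides `NA`) that mark an unknown
#'   parent; default `c("", "0", "UNK")`.
#' @param missing_parents what to do when a parent id has no row of its own:
#'   `"founder"` (default) appends it as a founder with the sex implied by
#'   its role, with a warning; `"error"` aborts.
#' @return A `pedigree` object.
#' @export
as_pedigree <- function(df, unknown = c("", "0", "UNK"),
                        missing_parents = c("founder", "error")) {
  missing_parents <- match.arg(missing_parents)
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  id <- trimws(as.character(df$id))
  if (anyNA(id) || any(id == ""))
    stop("missing individual id in row(s) ",
         paste(which(is.na(id) | id == ""), collapse = ", "))
  if (anyDuplicated(id))
    stop("duplicate id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))

  clean_parent <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% unknown] <- NA_character_
    x
  }
  sire <- clean_parent(df$sire)
  dam <- clean_parent(df$dam)

  sex <- if ("sex" %in% names(df)) .normalize_sex(df$sex) else rep(NA_character_, length(id))
  birth <- if ("birth" %in% names(df)) suppressWarnings(as.numeric(df$birth)) else rep(NA_real_, length(id))
  flock <- if ("flock" %in% names(df)) {
    fl <- trimws(as.character(df$flock))
    fl[fl == ""] <- NA_character_
    fl
  } else rep(NA_character_, length(id))

  # parents without a row of their own
  missing <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(missing)) {
    if (missing_parents == "error")
      stop("parent id(s) not in pedigree: ", paste(missing, collapse = ", "))
    warning(length(missing), " parent id(s) without a pedigree row added as founders: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
    add_sex <- ifelse(missing %in% sire, "M", "F")
    id <- c(id, missing)
    sire <- c(sire, rep(NA_character_, length(missing)))
    dam <- c(dam, rep(NA_character_, length(missing)))
    sex <- c(sex, add_sex)
    birth <- c(birth, rep(NA_real_, length(missing)))
    flock <- c(flock, rep(NA_character_, length(missing)))
  }

  # sex consistency with parental roles
  both <- intersect(unique(sire[!is.na(sire)]), unique(dam[!is.na(dam)]))
  if (length(both))
    stop("id(s) used both as sire and as dam: ", paste(both, collapse = ", "))
  role <- rep(NA_character_, length(id))
  role[id %in% sire] <- "M"
  role[id %in% dam] <- "F"
  clash <- !is.na(role) & !is.na(sex) & role != sex
  if (any(clash))
    stop("recorded sex contradicts parental role for: ",
         paste(id[clash], collapse = ", "))
  sex[is.na(sex)] <- role[is.na(sex)]

  ord <- .topo_order(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    sex = sex[ord], birth = birth[ord], flock = flock[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")

  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  bad <- which(!is.na(ped$birth) &
                 ((!is.na(si) & !is.na(ped$birth[si]) & ped$birth <= ped$birth[si]) |
                  (!is.na(di) & !is.na(ped$birth[di]) & ped$birth <= ped$birth[di])))
  if (length(bad))
    warning("birth time not later than a parent's for: ",
            paste(utils::head(ped$id[bad], 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "")
  ped
}

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1")] <- "M"
  out[x %in% c("f", "female", "2")] <- "F"
  out
}

# Kahn topological sort; errors on cycles naming an offending id.
.topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected involving id(s): ",
         paste(id[stuck], collapse = ", "))
  }
  ord
}

# 1-based parent indices into the sorted pedigree (0 = unknown)
.parent_idx <- function(ped) {
  list(sire = match(ped$sire, ped$id, nomatch = 0L),
       dam = match(ped$dam, ped$id, nomatch = 0L))
}

#' Read a studbook-style pedigree file
#'
#' Reads a delimited text pedigree (CSV/TSV/semicolon), auto-detecting the
#' delimiter, maps unknown-parent codes, and returns a validated,
#' topologically sorted [pedigree]. Column mapping is configurable; by
#' default common studbook column names are matched case-insensitively
#' (`id`/`animal`/`stud`, `sire`/`father`, `dam`/`mother`, `sex`,
#' `birth`/`born`/`year`/`birthdate`, `flock`/`location`/`site`). Birth
#' dates are reduced to the 4-digit year.
#'
#' @param path file path.
#' @param columns optional named character vector mapping the standard names
#'   `id`, `sire`, `dam`, `sex`, `birth`, `flock` to column names in the
#'   file, e.g. `c(id = "Stud", sire = "SIRE", dam = "DAM")`.
#' @param sep field delimiter; `NULL` (default) auto-detects among tab,
#'   comma and semicolon.
#' @param unknown,missing_parents passed to [as_pedigree()].
#' @param header does the file have a header row? Default `TRUE`.
#' @return A `pedigree` object.
#' @export
read_pedigree <- function(path, columns = NULL, sep = NULL,
                          unknown = c("", "0", "UNK"),
                          missing_parents = "founder", header = TRUE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    counts <- vapply(c("\t", ",", ";"), function(s)
      lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))), integer(1))
    sep <- c("\t", ",", ";")[which.max(counts)]
    if (max(counts) == 0L) sep <- ","
  }
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = header, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character", fill = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop("cannot parse pedigree file '", path, "': ",
                             conditionMessage(e)))
  std <- c("id", "sire", "dam", "sex", "birth", "flock")
  if (is.null(columns)) {
    synonyms <- list(
      id = c("id", "animal", "individual", "stud", "studbook", "name"),
      sire = c("sire", "father", "sire_id", "sireid"),
      dam = c("dam", "mother", "dam_id", "damid"),
      sex = c("sex", "gender"),
      birth = c("birth", "born", "year", "birthdate", "birth_date", "dob",
                "birthyear", "birth_year"),
      flock = c("flock", "location", "loc", "site", "herd", "population"))
    lw <- tolower(names(raw))
    columns <- vapply(std, function(s) {
      hit <- which(lw %in% synonyms[[s]])
      if (length(hit)) names(raw)[hit[1L]] else NA_character_
    }, character(1))
    if (anyNA(columns[c("id", "sire", "dam")])) {
      if (ncol(raw) < 3L)
        stop("cannot identify id/sire/dam columns in '", path, "'")
      # fall back on positional order id, sire, dam, sex, birth, flock
      columns <- setNames(c(names(raw), rep(NA, 6L))[1:6], std)
    }
  } else {
    columns <- setNames(columns[std], std)
  }
  pick <- function(s) {
    cn <- columns[[s]]
    if (is.na(cn) || !cn %in% names(raw)) rep(NA_character_, nrow(raw)) else raw[[cn]]
  }
  birth <- pick("birth")
  # reduce full dates to the 4-digit year
  birth_num <- suppressWarnings(as.numeric(birth))
  m <- regexpr("[0-9]{4}", birth)
  hit <- is.na(birth_num) & !is.na(birth) & m > 0
  birth_num[hit] <- as.numeric(substr(birth[hit], m[hit], m[hit] + 3L))
  df <- data.frame(id = pick("id"), sire = pick("sire"), dam = pick("dam"),
                   sex = pick("sex"), birth = birth_num, flock = pick("flock"),
                   stringsAsFactors = FALSE)
  as_pedigree(df, unknown = unknown, missing_parents = missing_parents)
}

#' Write a pedigree to a CSV file
#'
#' Writes the standard six columns (`id`, `sire`, `dam`, `sex`, `birth`,
#' `flock`), encoding unknown parents as empty fields. The output is
#' readable by [read_pedigree()].
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  n <- nrow(x)
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("<pedigree> %d individuals (%d founders, %d males, %d females)\n",
              n, founders, sum(x$sex == "M", na.rm = TRUE),
              sum(x$sex == "F", na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (n > 6L) cat("... and", n - 6L, "more rows\n")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  pedigree_stats(object)
}

#' Coancestry (kinship) matrix from a pedigree
#'
#' Computes coancestry coefficients by the tabular method: for individual
#' `x` with parents `s`, `d`, `f(x, y) = (f(s, y) + f(d, y)) / 2` for any
#' earlier `y`, and self-coancestry `f(x, x) = (1 + F_x) / 2` where
#' `F_x = f(s, d)`. Unknown parents contribute 0; founders are unrelated.
#'
#' @param ped a [pedigree].
#' @param ids subset of individual ids to return (default: all). The full
#'   pedigree is always used in the recursion.
#' @return A symmetric numeric matrix with `ids` as dimnames; entries lie in
#'   `[0, 1]` and the diagonal equals `(1 + F) / 2`.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(ids) && length(ids) == 0L)
    stop("empty id subset")
  idx <- .parent_idx(ped)
  K <- .kinship_tabular_cpp(idx$sire, idx$dam)
  dimnames(K) <- list(ped$id, ped$id)
  if (is.null(ids)) return(K)
  miss <- setdiff(ids, ped$id)
  if (length(miss)) stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
  K[ids, ids, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' The inbreeding coefficient of an individual is the coancestry of its
#' parents; it is 0 when either parent is unknown.
#'
#' @inheritParams kinship_matrix
#' @return Named numeric vector of inbreeding coefficients in `[0, 1]`.
#' @export
inbreeding <- function(ped, ids = NULL) {
  K <- kinship_matrix(ped)
  f <- pmin(pmax(2 * diag(K) - 1, 0), 1)
  names(f) <- ped$id
  if (is.null(ids)) f else {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
    f[ids]
  }
}

#' Equivalent complete generations
#'
#' Pedigree completeness per individual: the sum over all known ancestors of
#' `(1/2)^n`, where `n` is the generation distance, computed by the
#' recursion `EG_i = sum over known parents of (1 + EG_parent) / 2`.
#'
#' @inheritParams kinship_matrix
#' @return Named numeric vector of EG values (founders have 0).
#' @export
equivalent_generations <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- .parent_idx(ped)
  eg <- as.numeric(.eg_recursive_cpp(idx$sire, idx$dam))
  names(eg) <- ped$id
  if (is.null(ids)) eg else {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
    eg[ids]
  }
}

#' Generation interval
#'
#' Average age of parents at the birth of their progeny kept for
#' reproduction, i.e. over all parent-offspring links in which the offspring
#' itself has recorded progeny and both birth times are known. Each link is
#' one observation.
#'
#' @param ped a [pedigree] with birth times in years.
#' @return The mean interval in years, with attribute `n_links` (number of
#'   links used); `NA` if no link qualifies.
#' @export
generation_interval <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- .parent_idx(ped)
  has_prog <- ped$id %in% c(ped$sire, ped$dam)
  ages <- numeric(0)
  for (p in c("sire", "dam")) {
    pi <- idx[[p]]
    pbirth <- rep(NA_real_, nrow(ped))
    pbirth[pi > 0L] <- ped$birth[pi[pi > 0L]]
    keep <- has_prog & pi > 0L & !is.na(ped$birth) & !is.na(pbirth)
    ages <- c(ages, ped$birth[keep] - pbirth[keep])
  }
  if (!length(ages)) {
    out <- NA_real_
    attr(out, "n_links") <- 0L
    return(out)
  }
  out <- mean(ages)
  attr(out, "n_links") <- length(ages)
  out
}

#' Select a reference cohort
#'
#' Filters a pedigree to the individuals in a flock born inside an inclusive
#' window of birth times, the usual definition of a studbook reference
#' population. Either filter may be omitted; an explicit `ids` list
#' bypasses both.
#'
#' @param ped a [pedigree].
#' @param flock flock/location label to keep, or `NULL`.
#' @param years inclusive birth-time window `c(from, to)` (a single value
#'   selects one year/generation), or `NULL`.
#' @param ids explicit cohort ids overriding the filters.
#' @return Character vector of cohort ids with attribute `counts`
#'   (`c(males = , females = )`); warns when empty.
#' @export
reference_cohort <- function(ped, flock = NULL, years = NULL, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
    keep <- ped$id %in% ids
  } else {
    keep <- rep(TRUE, nrow(ped))
    if (!is.null(flock)) keep <- keep & !is.na(ped$flock) & ped$flock == flock
    if (!is.null(years)) {
      years <- range(as.numeric(years))
      keep <- keep & !is.na(ped$birth) & ped$birth >= years[1] & ped$birth <= years[2]
    }
  }
  out <- ped$id[keep]
  if (!length(out)) warning("reference cohort is empty")
  attr(out, "counts") <- c(males = sum(ped$sex[keep] == "M", na.rm = TRUE),
                           females = sum(ped$sex[keep] == "F", na.rm = TRUE))
  out
}

#' Structure statistics of a reference population
#'
#' Sex counts and ratio, mean inbreeding (overall and by sex), mean and
#' standard deviation of equivalent complete generations for a cohort, and
#' the generation interval of the whole pedigree.
#'
#' @param ped a [pedigree].
#' @param cohort ids of the reference cohort (default: all individuals).
#' @return A `pedigree_stats` list.
#' @export
pedigree_stats <- function(ped, cohort = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(cohort)) cohort <- ped$id
  miss <- setdiff(cohort, ped$id)
  if (length(miss)) stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
  f <- inbreeding(ped)[cohort]
  eg <- equivalent_generations(ped)[cohort]
  sex <- ped$sex[match(cohort, ped$id)]
  nm <- sum(sex == "M", na.rm = TRUE)
  nf <- sum(sex == "F", na.rm = TRUE)
  out <- list(n = length(cohort), n_males = nm, n_females = nf,
              sex_ratio = if (nm > 0) nf / nm else NA_real_,
              mean_F = mean(f), mean_F_males = mean(f[sex == "M"]),
              mean_F_females = mean(f[sex == "F"]),
              mean_EG = mean(eg), sd_EG = stats::sd(eg),
              generation_interval = as.numeric(generation_interval(ped)))
  class(out) <- "pedigree_stats"
  out
}

#' @export
print.pedigree_stats <- function(x, digits = 3, ...) {
  cat("Reference population structure\n")
  lab <- c(n = "Individuals", n_males = "Males", n_females = "Females",
           sex_ratio = "Ratio females/males", mean_EG = "EG",
           sd_EG = "Sd of EG", mean_F = "Inbreeding",
           mean_F_males = "Inbreeding of males",
           mean_F_females = "Inbreeding of females",
           generation_interval = "Generation interval")
  for (k in names(lab)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", lab[[k]],
                ifelse(is.na(v), "-", format(round(v, digits)))))
  }
  invisible(x)
}
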