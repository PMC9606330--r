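# Vocabulary normalization: verbatim drug strings -> ingredient + class via
# a synonym archive; reaction PTs -> SMQ codes via a user-supplied
# definition file (MedDRA is licensed, so no member PTs are bundled beyond a
# synthetic test fixture).

.drug_classes <- c("anti_VEGF_mAb", "anti_VEGFR_mAb", "VEGF_trap", "TKI",
                   "other_antiangiogenic", "non_target")

#' Canonicalize a drug name for archive lookup
#'
#' Case-folds, trims, strips punctuation, and collapses runs of whitespace,
#' so that e.g. \code{"Avastin."} and \code{"AVASTIN"} compare equal.
#'
#' @param x character vector
#' @return character vector
#' @export
canonical_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Load a drug-name archive
#'
#' CSV with columns \code{synonym}, \code{ingredient}, \code{class},
#' \code{region}: every generic name, brand name, and research code of an
#' ingredient maps to that ingredient and its pharmacological class. Loading
#' fails loudly if two rows canonicalize to the same synonym but different
#' ingredients, and every ingredient must list itself as a synonym.
#'
#' @param path CSV file
#' @return data.frame of class \code{drug_archive} with an added
#'   \code{canon} column
#' @export
read_drug_archive <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("synonym", "ingredient", "class", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug archive missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(df$class %in% .drug_classes)
  if (any(bad)) stop("unknown drug class: ",
                     paste(unique(df$class[bad]), collapse = ", "))
  df$canon <- canonical_name(df$synonym)
  clash <- tapply(df$ingredient, df$canon, function(v) length(unique(v)))
  if (any(clash > 1))
    stop("synonym collision across ingredients: ",
         paste(names(clash)[clash > 1], collapse = ", "))
  df <- df[!duplicated(df$canon), , drop = FALSE]
  self <- canonical_name(unique(df$ingredient)) %in% df$canon
  if (!all(self))
    stop("ingredient lacking self-synonym: ",
         paste(unique(df$ingredient)[!self], collapse = ", "))
  cls <- tapply(df$class, df$ingredient, function(v) length(unique(v)))
  if (any(cls > 1))
    stop("ingredient mapped to multiple classes: ",
         paste(names(cls)[cls > 1], collapse = ", "))
  class(df) <- c("drug_archive", "data.frame")
  df
}

# Damerau-free edit distance 1 test via utils::adist (substitution,
# insertion, deletion all cost 1)
.edit1_matches <- function(canon, archive) {
  d <- utils::adist(canon, archive$canon)
  which(d == 1L)
}

#' Normalize a verbatim drug name against the archive
#'
#' Combination products are split on \code{'/'} and \code{'+'} and each
#' component is looked up independently; the first mapped component wins for
#' the scalar return (use \code{map_drugs} for table-level mapping, which
#' stores one ingredient per drug row). An exact canonicalized match is
#' required unless \code{fuzzy = TRUE}, in which case a unique archive
#' synonym at edit distance 1 is accepted (misspellings occur in verbatim
#' fields; the conservative default avoids false mappings).
#'
#' @param verbatim character vector of verbatim drug strings
#' @param archive drug_archive
#' @param fuzzy logical, default FALSE
#' @return character vector: ingredient, or NA where unmapped
#' @export
normalize_drug <- function(verbatim, archive, fuzzy = FALSE) {
  stopifnot(inherits(archive, "drug_archive"))
  vapply(as.character(verbatim), function(v) {
    if (is.na(v) || !nzchar(trimws(v))) {
      warning("empty verbatim drug name")
      return(NA_character_)
    }
    comps <- strsplit(v, "[/+]")[[1]]
    comps <- comps[nzchar(trimws(comps))]
    if (!length(comps)) return(NA_character_)
    for (comp in comps) {
      canon <- canonical_name(comp)
      hit <- match(canon, archive$canon)
      if (!is.na(hit)) return(archive$ingredient[hit])
      if (fuzzy) {
        near <- .edit1_matches(canon, archive)
        ings <- unique(archive$ingredient[near])
        if (length(ings) == 1L) return(ings)
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Pharmacological class of an archived ingredient
#'
#' The mAb superclass covers \code{anti_VEGF_mAb}, \code{anti_VEGFR_mAb},
#' and \code{VEGF_trap} (intravenous biologics); the TKI superclass is
#' \code{TKI} alone (oral small molecules). See \code{\link{class_members}}.
#'
#' @param ingredient character vector of ingredient names
#' @param archive drug_archive
#' @return character vector of classes; unknown ingredients are an error
#' @export
classify_drug <- function(ingredient, archive) {
  stopifnot(inherits(archive, "drug_archive"))
  idx <- match(canonical_name(ingredient), canonical_name(archive$ingredient))
  if (anyNA(idx))
    stop("ingredient not in archive: ",
         paste(ingredient[is.na(idx)], collapse = ", "))
  archive$class[idx]
}

#' Ingredients belonging to a class or superclass
#'
#' @param archive drug_archive
#' @param class one of the archive classes, or the superclasses
#'   \code{"mAb"} (anti_VEGF_mAb + anti_VEGFR_mAb + VEGF_trap) and
#'   \code{"TKI"}
#' @return character vector of ingredients
#' @export
class_members <- function(archive, class) {
  stopifnot(inherits(archive, "drug_archive"))
  classes <- switch(class,
                    mAb = c("anti_VEGF_mAb", "anti_VEGFR_mAb", "VEGF_trap"),
                    TKI = "TKI",
                    class)
  if (!all(classes %in% .drug_classes)) stop("unknown drug class: ", class)
  sort(unique(archive$ingredient[archive$class %in% classes]))
}

#' Load SMQ definitions
#'
#' CSV with columns \code{smq_code}, \code{smq_name}, \code{scope},
#' \code{parent_code}, \code{pt_name}; one row per (SMQ, member PT). Rows
#' with empty \code{pt_name} declare an SMQ header without members (used for
#' the bundled top-level SMQ codes, since MedDRA content is licensed and
#' member PTs must be user-supplied).
#'
#' @param path CSV file
#' @return object of class \code{smq_definitions}: list with \code{smq}
#'   (one row per SMQ: code, name, scope, parent_code) and \code{members}
#'   (pt canon -> smq_code pairs)
#' @export
read_smq_definitions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("smq_code", "smq_name", "scope", "parent_code", "pt_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SMQ file missing column(s): ",
                         paste(miss, collapse = ", "))
  df$smq_code <- as.integer(df$smq_code)
  df$parent_code <- suppressWarnings(as.integer(df$parent_code))
  if (anyNA(df$smq_code)) stop("non-integer smq_code")
  if (!all(df$scope %in% c("narrow", "broad"))) stop("scope must be narrow/broad")
  smq <- unique(df[, c("smq_code", "smq_name", "scope", "parent_code")])
  if (anyDuplicated(smq$smq_code))
    stop("inconsistent metadata for an smq_code")
  orphan_parent <- !is.na(smq$parent_code) &
    !(smq$parent_code %in% smq$smq_code)
  if (any(orphan_parent))
    stop("parent_code not defined in file: ",
         paste(unique(smq$parent_code[orphan_parent]), collapse = ", "))
  members <- df[nzchar(df$pt_name), c("pt_name", "smq_code")]
  members$canon <- canonical_name(members$pt_name)
  structure(list(smq = smq, members = members), class = "smq_definitions")
}

#' @export
print.smq_definitions <- function(x, ...) {
  cat("<smq_definitions> ", nrow(x$smq), " SMQs, ", nrow(x$members),
      " member PT rows\n", sep = "")
  invisible(x)
}

#' Map a reaction PT to SMQ codes
#'
#' Returns every narrow-scope SMQ whose member set contains the
#' canonicalized PT, closed under the parent relation: membership in a
#' sub-SMQ implies membership in its parent.
#'
#' @param pt character vector of PT strings
#' @param defs smq_definitions
#' @return for a single PT, an integer vector of SMQ codes (possibly
#'   empty); for several PTs, a list of such vectors
#' @export
map_pt_to_smqs <- function(pt, defs) {
  stopifnot(inherits(defs, "smq_definitions"))
  narrow <- defs$smq$smq_code[defs$smq$scope == "narrow"]
  parent_of <- stats::setNames(defs$smq$parent_code, defs$smq$smq_code)
  one <- function(p) {
    codes <- defs$members$smq_code[defs$members$canon == canonical_name(p)]
    codes <- codes[codes %in% narrow]
    # parent closure (definitions nest at most a few levels)
    repeat {
      parents <- parent_of[as.character(codes)]
      parents <- parents[!is.na(parents)]
      new <- setdiff(parents, codes)
      if (!length(new)) break
      codes <- c(codes, new)
    }
    sort(unique(as.integer(codes)))
  }
  if (length(pt) == 1L) one(pt) else lapply(pt, one)
}

#' Map the drug rows of a report set against an archive
#'
#' Fills \code{ingredient} and \code{drug_class} on every drug row; rows
#' whose verbatim name has no archive match stay NA. Mapping counts go to
#' the log.
#'
#' @param x report_set
#' @param archive drug_archive
#' @param fuzzy passed to \code{\link{normalize_drug}}
#' @return report_set with mapped drug rows
#' @export
map_drugs <- function(x, archive, fuzzy = FALSE) {
  validate_report_set(x)
  if (!nrow(x$drugs)) return(x)
  # map unique verbatim strings once, then join back
  uverb <- unique(x$drugs$verbatim_name)
  uing <- normalize_drug(uverb, archive, fuzzy = fuzzy)
  ing <- uing[match(x$drugs$verbatim_name, uverb)]
  x$drugs$ingredient <- ing
  x$drugs$drug_class <- NA_character_
  hit <- !is.na(ing)
  if (any(hit))
    x$drugs$drug_class[hit] <- classify_drug(ing[hit], archive)
  x$log <- utils::modifyList(x$log, list(
    n_drug_rows_mapped = sum(hit),
    n_drug_rows_unmapped = sum(!hit)))
  x
}

#' Attach SMQ codes to the reaction rows of a report set
#'
#' Adds a \code{smq_codes} list-column to \code{x$reactions} (integer codes
#' per PT, parent-closed, narrow scope).
#'
#' @param x report_set
#' @param defs smq_definitions
#' @return report_set
#' @export
map_reactions <- function(x, defs) {
  validate_report_set(x)
  if (!nrow(x$reactions)) return(x)
  upt <- unique(x$reactions$pt)
  ucodes <- lapply(upt, map_pt_to_smqs, defs = defs)
  x$reactions$smq_codes <- ucodes[match(x$reactions$pt, upt)]
  x
}
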