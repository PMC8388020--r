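# Snips: the unit of dictionary storage. A snip is a byte string whose first
# byte may be a reserved opcode:
#   0x01 LOOKUP_LOCAL  value is the next entry of the context's local buffer
#   0x02 DELTA         "base|delta" - numeric delta vs another field or vs the
#                      previous value of the same context
#   0x03 CONTAINER     serialised record layout
#   0x04 SPECIAL       segmenter/codec-owned, subtype byte follows
#   0x05 reserved
#   0x06 escape        prefixes a verbatim payload whose first byte is 0x01-0x06
# Verbatim payloads therefore never *begin* with an unescaped control byte.

OP_LOOKUP  <- "\x01"
OP_DELTA   <- "\x02"
OP_CONT    <- "\x03"
OP_SPECIAL <- "\x04"
OP_ESCAPE  <- "\x06"
CTRL_CHARS <- c("\x01", "\x02", "\x03", "\x04", "\x05", "\x06")

#' Encode verbatim payloads as snips (vectorised)
#' @keywords internal
snip_verbatim <- function(payload) {
  esc <- substr(payload, 1L, 1L) %in% CTRL_CHARS
  if (any(esc)) payload[esc] <- paste0(OP_ESCAPE, payload[esc])
  payload
}

#' Decode a snip back to its components
#'
#' Returns a list(op, payload): op one of "VERBATIM","LOOKUP_LOCAL","DELTA",
#' "CONTAINER","SPECIAL". Round-trips snip_verbatim() and the op constructors.
#' @keywords internal
snip_decode <- function(s) {
  first <- substr(s, 1L, 1L)
  if (first == OP_ESCAPE) return(list(op = "VERBATIM", payload = substr(s, 2L, nchar(s))))
  if (first == OP_LOOKUP) return(list(op = "LOOKUP_LOCAL", payload = substr(s, 2L, nchar(s))))
  if (first == OP_DELTA) return(list(op = "DELTA", payload = substr(s, 2L, nchar(s))))
  if (first == OP_CONT) return(list(op = "CONTAINER", payload = substr(s, 2L, nchar(s))))
  if (first == OP_SPECIAL) return(list(op = "SPECIAL", payload = substr(s, 2L, nchar(s))))
  if (first == "\x05") stop("reserved opcode in snip")
  list(op = "VERBATIM", payload = s)
}

snip_delta <- function(delta, base = "") {
  paste0(OP_DELTA, base, "|", format(delta, scientific = FALSE, trim = TRUE))
}

snip_special <- function(subtype, payload = "") paste0(OP_SPECIAL, subtype, payload)

# ---------------------------------------------------------------------------
# Containers: structural snips describing a record layout.
#
# new_container(items = list(list(name=, sep=, prefix=, translator=)),
#               repeats = 1, rep_sep = "")
# Reconstructing a container emits, `repeats` times:
#   prefix_i || value(ctx_i) || sep_i   for each item i
# with rep_sep between repetitions. Serialisation is deterministic, so
# identical layouts dedupe to a single dictionary entry.
# ---------------------------------------------------------------------------

new_container <- function(items, repeats = 1, rep_sep = "") {
  if (length(items) > 255L) stop("container exceeds 255 items")
  if (repeats < 0 || repeats >= 2^32) stop("container repeats out of range")
  items <- lapply(items, function(it) {
    list(name = it$name,
         sep = if (is.null(it$sep)) "" else it$sep,
         prefix = if (is.null(it$prefix)) "" else it$prefix,
         translator = if (is.null(it$translator)) 0L else as.integer(it$translator))
  })
  structure(list(repeats = repeats, rep_sep = rep_sep, items = items),
            class = "gcol_container")
}

# length-prefixed field: "<decimal len>:<bytes>"
.cfield <- function(s) paste0(nchar(s, type = "bytes"), ":", s)

container_serialize <- function(c) {
  body <- paste0(format(c$repeats, scientific = FALSE, trim = TRUE), ";",
                 length(c$items), ";", .cfield(c$rep_sep), ";",
                 paste(vapply(c$items, function(it) {
                   paste0(.cfield(it$name), .cfield(it$sep), .cfield(it$prefix),
                          it$translator, ",")
                 }, character(1)), collapse = ""))
  paste0(OP_CONT, body)
}

container_deserialize <- function(s) {
  if (substr(s, 1L, 1L) != OP_CONT) stop("not a container snip")
  txt <- substr(s, 2L, nchar(s))
  pos <- 1L
  take_until <- function(ch) {
    i <- pos
    while (substr(txt, i, i) != ch) i <- i + 1L
    out <- substr(txt, pos, i - 1L)
    pos <<- i + 1L
    out
  }
  take_field <- function() {
    len <- as.integer(take_until(":"))
    out <- substr(txt, pos, pos + len - 1L)
    pos <<- pos + len
    out
  }
  repeats <- as.numeric(take_until(";"))
  nitems <- as.integer(take_until(";"))
  rep_sep <- take_field()
  if (substr(txt, pos, pos) != ";") stop("corrupt container snip")
  pos <- pos + 1L
  items <- vector("list", nitems)
  for (k in seq_len(nitems)) {
    nm <- take_field(); sp <- take_field(); pf <- take_field()
    tr <- as.integer(take_until(","))
    items[[k]] <- list(name = nm, sep = sp, prefix = pf, translator = tr)
  }
  new_container(items, repeats = repeats, rep_sep = rep_sep)
}

# Dictionary serialisation: escaped snips joined by 0x00 terminators.
dict_serialize <- function(entries) {
  if (length(entries) == 0L) return(raw(0))
  unlist(lapply(entries, function(e) c(charToRaw(e), as.raw(0L))), use.names = FALSE)
}

dict_deserialize <- function(r) {
  if (length(r) == 0L) return(character(0))
  if (r[length(r)] != as.raw(0L)) stop("corrupt dictionary section")
  zero <- which(r == as.raw(0L))
  starts <- c(1L, zero[-length(zero)] + 1L)
  out <- character(length(zero))
  for (k in seq_along(zero)) {
    if (starts[k] > zero[k] - 1L) out[k] <- ""
    else {
      s <- rawToChar(r[starts[k]:(zero[k] - 1L)])
      Encoding(s) <- "latin1"
      out[k] <- s
    }
  }
  out
}
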