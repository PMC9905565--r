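# Guess comma vs tab from the header line.
guessDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

# Split "+"-separated layer strings into a list of character vectors.
splitLayers <- function(x) {
  out <- strsplit(as.character(x), "\\s*\\+\\s*")
  lapply(out, function(v) v[nzchar(v)])
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
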