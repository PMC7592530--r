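# Minimal KGML writer for fixtures: entries is a data.frame (id, name,
# type), relations a data.frame (entry1, entry2, type); groups maps entry
# id -> component ids.
write_kgml_fixture <- function(path, entries, relations, groups = list(),
                               metabolic = FALSE) {
  lines <- c('<?xml version="1.0"?>',
             '<pathway name="path:test" org="hsa" number="99999" title="fixture">')
  for (i in seq_len(nrow(entries))) {
    id <- entries$id[i]
    if (as.character(id) %in% names(groups)) {
      lines <- c(lines,
                 sprintf('  <entry id="%s" name="%s" type="%s">',
                         id, entries$name[i], entries$type[i]),
                 sprintf('    <component id="%s"/>', groups[[as.character(id)]]),
                 "  </entry>")
    } else {
      lines <- c(lines, sprintf('  <entry id="%s" name="%s" type="%s"/>',
                                id, entries$name[i], entries$type[i]))
    }
  }
  for (i in seq_len(nrow(relations))) {
    lines <- c(lines,
               sprintf('  <relation entry1="%s" entry2="%s" type="%s"><subtype name="activation" value="--&gt;"/></relation>',
                       relations$entry1[i], relations$entry2[i], relations$type[i]))
  }
  if (metabolic)
    lines <- c(lines,
               '  <reaction id="77" name="rn:R00001" type="irreversible"><substrate id="3" name="cpd:C00001"/></reaction>')
  lines <- c(lines, "</pathway>")
  writeLines(lines, path)
  path
}
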