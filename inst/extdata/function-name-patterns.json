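{
  "comment": "Case-insensitive regular expressions classifying product function names. 'unknown' takes precedence over 'vague'; names matching neither are 'specific'. Editable; seed lists cover common annotation boilerplate.",
  "unknown": [
    "hypothetical protein",
    "uncharacterized protein",
    "^orf\\b",
    "\\bDUF[0-9]+",
    "domain-containing protein$",
    "^putative protein$",
    "^predicted protein$",
    "^conserved protein$",
    "protein of unknown function",
    "^unknown\\b"
  ],
  "vague": [
    "^(putative |probable |predicted )?(MFS |ABC |membrane )?transporter$",
    "^(putative |probable |predicted )?oxidoreductase$",
    "^(putative |probable |predicted )?regulatory protein$",
    "^(putative |probable |predicted )?(hydrolase|transferase|isomerase|ligase|lyase|kinase|phosphatase|dehydrogenase|reductase|permease|esterase|protease|peptidase|metalloprotease)$",
    "^(putative |probable |predicted )?transcriptional regulator$",
    "^(putative |probable |predicted )?(DNA|RNA)-binding protein$",
    "^(putative |probable |predicted )?(inner |outer )?membrane protein$",
    "^(putative |probable |predicted )?(lipo|exported |secreted )?protein$",
    "^(putative |probable |predicted )?enzyme$"
  ]
}
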