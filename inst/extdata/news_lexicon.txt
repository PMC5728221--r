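# News-theme lexicon for the heuristic topic labeler: terms typical of
# media reporting on the opioid crisis.
news
report
reports
police
seized
seizure
overdose
overdoses
deaths
death
crisis
epidemic
warning
warns
officials
arrested
arrest
bust
investigation
media
article
breaking
story
laced
counterfeit
dea
health
public
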