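# Selling-argument lexicon: promotional terms signalling commercial intent.
# Core terms:
buy
discount
price
# Extension terms (maintainers' additions, versioned here; not part of the
# core set above):
cheap
sale
order
purchase
shipping
delivery
offer
deal
wholesale
supplier
vendor
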