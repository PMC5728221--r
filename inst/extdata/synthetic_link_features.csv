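url,platform_kind,offers_no_prescription,has_drug_price_list,redirect_unresolved
https://ads.example/post/101,classifieds,FALSE,FALSE,FALSE
https://ads.example/post/102,classifieds,FALSE,FALSE,FALSE
https://ads.example/post/103,classifieds,FALSE,FALSE,FALSE
https://ads.example/post/104,classifieds,FALSE,FALSE,FALSE
https://ads.example/post/105,classifieds,FALSE,FALSE,FALSE
https://ads.example/post/106,classifieds,FALSE,FALSE,FALSE
https://rx-shop.example/fnt1,pharmacy_storefront,TRUE,TRUE,FALSE
https://pills-now.example/order,unknown,TRUE,FALSE,FALSE
https://redirect.example/x,unknown,FALSE,FALSE,TRUE
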