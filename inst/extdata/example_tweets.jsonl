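{"id":"1001","text":"Police report: counterfeit fentanyl pills seized in major bust, officials warn of overdose risk","created_at":"2015-06-02T10:00:00"}
{"id":"1002","text":"Fentanyl crisis: news report details spike in overdose deaths across the state","created_at":"2015-06-02T10:05:00"}
{"id":"1003","text":"Breaking news: DEA warns counterfeit pills laced with fentanyl are driving overdose deaths","created_at":"2015-06-02T10:10:00"}
{"id":"1004","text":"Health officials report fentanyl overdose epidemic worsening, police investigation underway","created_at":"2015-06-02T10:15:00"}
{"id":"1005","text":"Buy fentanyl online no prescription best price discount shipping https://rx-shop.example/fnt1","created_at":"2015-06-02T10:20:00","urls":["https://rx-shop.example/fnt1"]}
{"id":"1006","text":"RT @dealer42: Buy fentanyl online no prescription best price discount shipping https://t.co/abc1","created_at":"2015-06-02T10:25:00","retweeted":true}
{"id":"1007","text":"Buy fentanyl online no prescription best price discount shipping https://rx-shop.example/fnt1","created_at":"2015-06-02T10:30:00"}
{"id":"1008","text":"Cheap fentanyl patches for sale, wholesale price, discreet delivery https://pills-now.example/order","created_at":"2015-06-02T10:35:00","urls":["https://pills-now.example/order"]}
{"id":"1009","text":"Opinion: what the opioid epidemic tells us about public health in america","created_at":"2015-06-02T10:40:00"}
{"id":"1010","text":"Fentanyl seizure at the border: police report record haul, news at nine","created_at":"2015-06-02T10:45:00"}
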