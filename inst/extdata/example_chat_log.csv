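time,sender,message
36:38,nick,"So, I think the salt is really low importance."
37:00,kate,"i don't think the aircraft compass or motor oil are very useful"
37:05,nick,"kate, sun umbrella is high (we need shade!)"
37:11,kate,"i would put umbrella and food next after water"
37:16,nick,"Well, I think the compass works regardless, but yeah."
38:13,jeral,"Mirror is high because it's a signal"
38:17,jeral,"You can reflect the sun"
38:25,greg,"depends how big it is"
38:29,kate,"well yeah"
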