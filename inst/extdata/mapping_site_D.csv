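"local_statement_id","catalog_statement_id"
"D_L001","PAT01"
"D_L002","PAT02"
"D_L003","PAT03"
"D_L004","PAT04"
"D_L005","PAT05"
"D_L006","PAT06"
"D_L007","PAT07"
"D_L008","PAT08"
"D_L009","PAT09"
"D_L010","PAT10"
"D_L011","PAT11"
"D_L012","PAT12"
"D_L013","PAT13"
"D_L014","PAT14"
"D_L015","PAT15"
"D_L016","PAT16"
"D_L017","PAT17"
"D_L018","PAT18"
"D_L019","PAT19"
"D_L020","THX01"
"D_L021","THX02"
"D_L022","COG01"
"D_L023","COG02"
"D_L024","COG03"
"D_L025","COG04"
"D_L026","COG05"
"D_L027","COG06"
"D_L028","COG07"
"D_L029","COG08"
"D_L030","COG09"
"D_L031","COG10"
"D_L032","RSK01"
"D_L033","COM01"
"D_L034","UNI01"
"D_L035","UNI02"
"D_L036","UNI03"
"D_L037","UNI04"
"D_L038","UNI05"
"D_L039","UNI06"
"D_L040","UNI07"
"D_L041","UNI08"
"D_L042","UNI09"
"D_L043","UNI10"
"D_L044","ENM01"
"D_L045","ENM02"
"D_L046","ENM03"
"D_L047","ENM04"
"D_L048","ENM05"
"D_L049","ENM06"
"D_L050","ENM07"
"D_L051","ENM08"
"D_L052","ENM09"
"D_L053","ENM10"
"D_L054","ENM11"
"D_L055","RTC01"
"D_L056","RTC02"
"D_L057","RTC03"
"D_L058","RTC04"
"D_L059","RTC05"
"D_L060","RTC06"
"D_L061","RTC07"
"D_L062","RTC08"
"D_L063","RTC09"
"D_L064","RTC10"
"D_L065","RTC11"
"D_L066","RTC12"
"D_L067","RTC13"
"D_L068","RTC14"
"D_L069","RTC15"
"D_L070","RTC16"
"D_L071","RTC17"
"D_L072","RTC18"
"D_L073","RTC19"
"D_L074","EDU01"
"D_L075","EDU02"
"D_L076","EDU03"
"D_L077","EDU04"
"D_L078","EDU05"
"D_L079","EDU06"
"D_L080","INF01"
"D_L081","INF02"
"D_L082","INF03"
"D_L083","INF04"
"D_L084","INF05"
"D_L085","ALM01"
"D_X001",""
"D_X002",""
"D_X003",""
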