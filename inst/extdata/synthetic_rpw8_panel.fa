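>rpw8_consensus synthetic
GKQRTCALLIAYADKAGSHNVTKDTLRRSILEALYGVNLSMVYLPDSFPKTKISSSGSPMCQSTNLKKVS
KPRYGLVDGENDEHTISTAITQAIFGLSTVVAVMGLIQIIHEKGESGRLCSPSMYAGEAVRDWQHAFVKG
DIREANIEES
>rpw8_var1 synthetic
GKQRTCAVLLAYADKAGSHNVSKDTLRESILEALFGVGLSMVYLPDSFPKSSISSSASPMAQATNLKKVS
KPRYGMLDGENDEHTIDTAIAQAIFAMSTVVCVMGLIQIIHEKGESGRLCSFNLYAGEGVRDWQHAFVKG
DMREANIEES
>rpw8_var2 synthetic
GKSRTCSLIIAYADKAGSHNATKDTLRRSILEGLYGVNLSFTYLPDGFPQTKLSSSGSPMCQSANLQKVS
KSRYGLVDAENNNYTISTAITQTFFGLSTVVAVMGLIQIIHEKGESGRLCSPSQYAGEAVRDWQNAFTKN
DIREANIEES
>rpw8_var3 synthetic
GKQRTCTLLIAYADEAGSHNMTKDTLRRSIIEALYSINLSMVYLPDSFPETKISDSGSPMCQSTNMKKVS
RPRYGLVDAENDEHTISTAITQAIFGVSVVVAVMGLIQIIHEKGESARLCSPGMYSSESVRNWQEAFLKG
DIREGKIEES
>rpw8_var4 synthetic
GKQRTCGLLIAYADKAGSHNVTKDTLHQSILESLYGVNLSMVFLPDSFPKTKLSSAASPFCQDTNLQEVS
KPRYGLVDGENDRHTISTAITQAIFNLDTVVAVMGLIQIFQESGESGRLCSPSFYSGEAVRDWQHAFTKN
NIREANIEES
>rpw8_var5 synthetic
GKQRTAALLITYADNANKHNVTKDTLRRSILEALYGVSLSMVYLPDSFPKTKISSSGSPMAQGTNLEKVS
KFRYGLVDNENDEHTISSVITDAILGLSTVLAVMGLIQIIHEKGNSGQLCSPSMYAGEVVRDYQHAWTQG
DIREANIEES
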