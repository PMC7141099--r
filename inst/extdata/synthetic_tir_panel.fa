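>tir_consensus synthetic
VVEFVGVHMSRWASQPLPEEFTEKQEGRYQSPMRKAVQEGSDQYERIMTVMKLRYSEEICGTLITPEPTP
GQTYPAQDSRGGYLCIKTEKVALNESVDLRASCPWGTAIDIESKLDEAYVVDASISADVCPVRANGLPPS
VSGFEASAEASEGRAWVKRTKFFAFEATLL
>tir_var1 synthetic
VVEFVGVHMSRFASQPLGEEFNEKQEGRHQSPMREAVQENSDRYEEIMTVMQLRYDEELCGTLITPEPTP
GETFMAQDSRGGHLCIQTEKVALNESVDLRAACPWGTAIDIESKLSEAYVVDGEISADLCYVRANGLPPS
VAGFEASGEASEARAWVKRTKFFAFEASLL
>tir_var2 synthetic
VVKFVGIHMSRWASQPLPNEFTEKQEGRYQSPMRKSVQDGSDHYERMFTVMEFRYSDNICGTLITPESSP
GQTYPAQDSRGGYLAIKVEKVALNESVDVRASCPFGTAIDVESKLDEAYVMDASLSVDVCPVRANGLPPS
TSGFEASAEAGEGRAWVKRTRFFAWEATLL
>tir_var3 synthetic
VVEFVGVHMTRWASNPMPEEITEKQEGQHQSWIRKAVRESSDEYERIMTVMELRYSEEICGTLVTPEPTP
GQTYPAKDSKGGYLCIKTEKVTMNESVDLQASAPWGTAIDIESKLQEAYVVDASISADACGVRANGLPWS
VQGFEASAEASEGKAWVQRTKFFAFEATLL
>tir_var4 synthetic
TVEFVGVHMSRWASQPLPQEYTEKQEGRYQNPMRSAVQEGSEQYERLMTVMRLKYSERIANTLITPEPTP
GQTHPAQDSRGGYICINTEKVCLNHSVDVRSSCPWGTAIDIESKLDEAYVADASISADVCPVRAEGLPPS
VSGFEASASASEGRAYVKESKFFAFEAALL
>tir_var5 synthetic
VVNFTGVHMSRWASQPLPEKFTEKQNGRFQSPMRKAVQEGSSQYERVMAVMKLRYKEEICGTLFAPEPTP
GQTYPAQDSRGGYMCIKTESVALNHSVDMRASCPWGTAIDIESKLDEAYVVDASISASACEVKANGLPPS
VSSFSANSEASEGRSWVKHTKFFSFEATLL
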