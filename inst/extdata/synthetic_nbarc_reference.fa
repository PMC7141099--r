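>ref_CNL_1 class=CNL synthetic
TRQRTLPEGQMKSSLAQDCTIARAKGMGGVGKTTVLTRFLKSKRHEFREMDFNGWGFALIVTGGRTMFSR
KATNSIAFGQLREAYTEIEVVGVKAKRFLIVLDDVWSFDTRFKVVFEGLGGACDSNGGCVVMIVGVHVLL
QLADAEHKCRGLPLALTRIESLAIQWQEEIGTLIDNKNAKAKMSDNSKRICFLYCALFPPPEVSKVYTDS
MAFYSLCALRVIEIDGELCSVKMHDLVRDMGLEDKSQGSGAISYKVGRGCAKEAPVACVNRPKRKKGDKF
>ref_CNL_2 class=CNL synthetic
TEQRTLPEGQMKSSLAQDCNITRARGMGGVGKTTVLTRILKGERREFNEMDFNGWAFALIVTGGHTVFSR
KATNSISLGQMQETYTEMEVVGVKAKRFLMVLEDVWSFNTRFKAVMESLGGAADDNGNAVVFIVGVHVLL
QMADAEHKCRALPLALTRIESIAIQYQESIGTFIDNKNAKAKMEDNSERICFVYCGLFPPPNVSKVYTDT
MAFYSLAALRVIEISGELCSVEMHDLVRDMGMEDKDQGSGAISYKVGRGCAKEAPVAAMNEAKRKKGDKF
>ref_TNL_1 class=TNL synthetic
VSIYTLDKAIAEMWSGVSTLKPLEVGMGGVGKTTRFHLQIQARAAAAGMFTPILIAAPREILSQTAEQAE
KGGRWDAQEMARLKVELGVVENGNEKRFLIVLDDVWGADNGFNDSTIVFNFDGPRVIVRHQSMWFRRSDL
SDDEKRLLIVGLPLALSISMPVLRYLGRYGPLNDADDNAKQNKPKTGKIACFLYCALFPYNSLAVRLPMY
HATACESWALDYILLMLSCVVKMHDLVRDMEFAVGPQQDRDDMVQVPRAQSVPELVLERVSEELSRRAFP
>ref_TNL_2 class=TNL synthetic
VSIYTLQKAIAEMYSGVSTLQPLEVGMGGMGQTTRFNLQLQARAAAAGMFTPILIAAPHEIVSENAEKAE
KGGRWDAQEMARLNVSLGVVENGNEERFLIVLDQMWGGDNGFTDSTIVFEFDGPRVIVRHQSMYFRRSNL
SDNEERLLIVGLPLALKISMIVLRYLGRHGPLNQANDSAKDNKPKTGKVACFLFCALMPYNSLAVRLSMY
HATACESFALDYILFMLSCIVKFYDLVRDMEFTVGPKQDRDDVIQVPRAQSVPKLVIERVGEKLSRRSFW
>ref_NL_1 class=NL synthetic
SEHTQNGNATYKQVDVQVEVERRSDGMGGVGKTTVFSSQSVDWVESLSDVFKADMNIMEVDLGELVNAGK
SESSASRMSLDLYPPLTAEPAEAPTKRFLIVLDDVWATAKHLAKLFFPKFVNATAIVSEVIVNIKVDNKS
IVMQFAIKEMGLPLALELLPKVPNKQIPHYYADCHAKYTDSVETFEDFIHCFLYCALFPDCTLLSVDEFT
VKEEKAVRDVSGAKRASQGSVKMHDLVRDMSRKITGPKNADGLTRPEGTTCAQLPPRTDTIDYDDFCKEA
>ref_NL_2 class=NL synthetic
SEEAENGNATYKQVDVQVQVERHANGMANVGKTTVFSSQSVDWVEELSDMFKADMNIMEVNLGQLVNAGE
SESSASRMSLDLFPPLTAEPAEAQTKRFFITLDNVWVTAKHLAKLFFEEFVNATCLISEVIVNISINNKS
IVMQFAIKEMGLKLAVELLPKVNNKDLFHWYADAHAKYTDSVETFEDFIHCIIYCALFPQCTLLSVDEFT
VKEEKAVRDVSGANHASQGKVKMHDLVRDMSNKITGPKTADALTRPEATTAAQLPPRTSAIDYDNFCKEA
>ref_RNL_1 class=RNL synthetic
VAKPLSKALSYSDGEMQQEKAVSSAGMGGVGKTTMNSSAEDKVATTVDAPCVEGSNRTKIMSDVSADGNP
AELKREDAGSLLNPFICPKVIISFEKRFLIVLDDVWRAGNTNTDMPKLASDFPFTSIKFEVPPLMDLDSR
GAYAFLVAPEGLPLALLLIVPPMSYESSTFYASLEIDKSEYGGIPTERFGCFLYCALFPLLKKSIVGLVC
ESFAIVTEPHSTRLNEAQPLVKMHDLVRDMPFYKSMCALELHALCWYTVRFPQGDSEQDVIERVADSIIG
>ref_RNL_2 class=RNL synthetic
IAKPLNKALSYSDGKMQQEQAVSSAGMGGVGKTTMDSSAEDKVATTVDAPAVEASNQTRIMSDVSADGNH
AELKREDAGSLLNPIICPQVVISFESRFVILLDDVFRAGNTNTSMPKLSSNFLWTSIRFNMPNVMDLDSR
GAFSFLAAPEGLPLALLLIVPPLSHESKTFYASLEMSKSEYGGIPTERFGCFLYCALWGLLKKSIVGLVA
ESFAIVTEPHSTRFKEAQKLVKMHDIVRDMPFYQTMCALELHVLCWYTLRFPQGDAKKDVIEHVADSIIG
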