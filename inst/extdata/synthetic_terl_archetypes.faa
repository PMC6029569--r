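>Sf6
MLGKIVKNQLEFEAVIEDVEDLKDARGDQNARLALPMRSNKFMPVAIGNSMGLVASIFSYARYDFVKGMK
AGEKFLHQHDDAVLCILIQVKMNTSAVAVVKNIPFRYAALGQERDCRSKGMTWRIVYIRVLMDEELDTKQ
KEPTPERSRHLITEGADKDVTTNAIRGLQRAEPESDQPNKINLKIGATRGRSELQPSALPQENYGHQRHM
SEPLLIVAPKFEHQHINMDVKANVWEWGRIDIFPGSRLDADWVSLSGNTEKKRDGQLMKDREYGRLITIL
QGVIQFPALQKMRVINPSPGEIAEIFAASITLREAIICEMWVDSGALEYRAMIDEADDLLEAAGLLYCPA
QYDKNGGETMVYDGSEDATKGQAPTSAPGPSMAYDSDYDIVKMYAYTAPKCQINEPVMND
>933W
MARRCNIGDKAAITCVMQPKEIAGSVGGLKLTPEDPLNTQLFISLQAGELLLNVLKESNHGDGFQSKAPR
MEDWKPLGGMTFGTSLGEERIAINDGVAGLGSIEYRVPDKLNTKPKQRAMDKKPMSISKQMTVIPVAEKS
NIADGLVLLFLVGDVGAPQLRTTCLLGPKRRALITQFWDLLYASTCESSTVASKEENAPVELLQGVLSPG
NIGGEVVIELGLNTYHLYNAAAENLIRIDAATTDTQVALSVESIHTEVAIGCTYKAKFFAVLVIGKFARD
IKSNTGPQGIKKDMPEANLDTVRASQGKEIDLAVRKTVAALAMPLRGKYKNFAESPKSKHFKGQMEDGDK
DRILKTSISDNLEEAHESLTNLLVYKVWATVEAFPSVGLGVVGVRRSDDKHDVGDGVWPFLVEMKEPQDV
WDHRMMEAGE
>T4
MSYPENMTSSEKYYLQQEKVQPSKSASKQLPLPRRWRFRYSGKCNICAELQAQGTLEAQINKSLEHVDTF
RPQFGSHLELSDLYSPEVEGYHFAPKVAGLRSPKEESGGTNAFLRFFMITKLLNAKMMEAGYKPPRIHQT
QFVQDLVYRQDQESSVRKVPSYLGVAGPPWEKAVLPIFLSAASDKGPAANRSAIEAAEYIANTVESMQQN
LQRDTPITLCGEFGSPVPRLALKNPVEYIEVAFNDRKYGGQDQGQEVADRVLRDRGKPPLVLDQSPCVEQ
IADQPVDWTAGKMRDPLDSSQTRVCDNPLEKDANRREIYSDFFWNSISVENSDCKSKDIEVFVDSKSDVD
VHVAGSQHGLRKTRILSALLRRLTTLLYMGPTTCNDGIIHTEGLGLCIGPGSFEIGAERAGKEKDVRAAI
KYTEFWSEGSGRDVWKNVMKPDCGIAEPIRKLQFRVGTEAKLLLAFTYYMEVQGVLEHLLTQQQFQRGDA
TKQNYSYSVREACGEEHAFIATYLAQYICKSDSLGCPLIELAEESLGATVKLSDLRTDISADNEQGHSNL
SMRLNDMEQDHSSSQGFRARDPTVMYHIGCDGVPEPKPNYILAQLMPAGE
>P22
MLNWYVGTVNPDRDDGGFAYVISSLGKWKGFGYTYTQPADLLDMKGTRGAARSSAYVHAHNLTVNNLGER
QSSQKTRNGEHATTTRMNPINHIVNANYTLLRLKEDWRKNWDVGDGTLLHLITKANIYVGKSGECEPFTQ
AALINFQSVDRCMVQTKGGECALDATVYSTRQIFTTEFVAKEPHPIGIVCKLDSYDKLTILPFREKENIA
CRQRTLAFLWSTSDFKVERAKRYYVFYDYHKECLIKQHRRNKIRRSDCWPEPGPKALATEAPNNAAYFSD
TFQLQIADKYLGPGFGNTPIFIVQFADTSPDHFVGIEEGSKTKNKSGDDNQNQATKLVGILDTGPDEEAN
PAALQVQFIRLSLGEPVSFFAWILVSKQFSWHVLYTDSALWNYDGSSVKSTQCTAEEEVSLRIKAIAEDG
GEDMVFMHESCPPTKSGRSNYLVGSFRVKLRRAALELLYDPKTQKDVDEKIKEYTLDLKVAWRRANRVLK
KYSSNQSLT
>lambda
MNSLDEAAGADLRDKDVKRGPAGIGLLELSMAVLILPDGILSKYIINRTLLRVGAPLIFRIPLARFPTEA
SIKISLTLRHALQTHEYVVQLAILPLTMISDEEITFATIQTVELNKGFVAENSRILLSAYDAIGSFPQLI
ILKHSPEMFFTGRDHKLMQSYKEADIMQELSYDISTHGPVLGISSANYINLKLKIMMAMASTFEKWDKLN
PTEPAPLPYINERTGGKNEDQATNDILLKGVTQGVYYIEAFLGRADLIAVLMMDANPISGFSFYVPDGEE
DIVLALEFGTGYLMIEKVIRAESEMKCSASKGIMEAYIENLWKNAFIGDGAAVEARAHALNQIKNASSAG
RKKAARWEPWFHLEYGQVPRFHMRTYGPWQFAEMNESSACMQNSLKEGEENHELSPLIVDYNVGYTEAPA
YLSGAPELAHAFREFQDKTPLRIEISQGMWGALYLWEDLEPLAFSEKPSKRGVEYAHAALMMQNSQYAII
FKAYVDELSECTDGRDSYEENQFYGTLRGPPTPWVLEDLDTLPEIAEAVRVLCVEEVVAILLAALDDEEP
LAGRIVWTPLIIKKELREKVHGPFNMVVSAFVASRQWAPFIHVLRLRFTRTALIRMMRWRLSEELMKFTD
TITSSSKMMIQ
>HK97
MMLADKSSVPPLHVTGAHPNALSFVDLMTIDKRFKILHTNIINPATAYTDHIRAVTIPAVQYPTKLYGMR
GQACELEGTNETDARLKQKYKMYEADLQAEDFVIMISCAKDKLIIATQDMGIVVKNLTLFYGTFEKASAH
IELKRDRGRLILVSEFTALTVPEQKDLQQTMAVIGEPYKWPAIATGTPQINVDKEAIVLSYCLVDQESET
VLNFRLYKPAKSGCAGTKDEFSRLAYAGLVGTYSANKDLTKIFSLQMAKIVTIAGCLLIGEYKFYVQEAE
SSNVPGALLGGPNADIQALEKLLGVDDVAVQMGVRRIPDLTVLLAYLKVDILYGVYRREPPETIIRGLYH
LGGAYEAFEKIKRGFIQNAYLGRRVWSSHREEGIHYQRGDAFEGAHDSSTSERRSATQKLSKDCDKPVAF
WRQA
>P2
MEHMPEGGHYLAIIQIQIGQLVYLGHEPELALPLRRRNRLVRIKVGSSSRTWLTTHYVQTGERAANFHGS
GFSIAHDIEDNYVEKDGKLAEQDLFQEVFLGGASLGFSILFGQKIQGEMWRKPCLKTNFDKLSEMWIQEM
ANFAQTSLENLLMKRYLTKPLNFQVEILGFSFFMSKYTQIWFQHSLHVVMLVNAVVIAEGPFEPGQQLLS
TRWTTAESTWSVGFKDLYNKSTLSATERLIKQAESRLKFPYFNETEVLPRIEARKELQPHQAAKEIEIRR
RNEGPRRKSALDTLLNLLTKFHNHSDALPSLHRCMALLTQQEKAVASPKQTCDKIQSPSKQSIEVDLGIP
SLFTTGGVEKGEVLLLARQDIIISDKLRTSYSFLRLTRKTDGYYKLMLILANPNLPTCIMPRKQPTAWMN
NTLTTIKGLNLSPRQFSCPLTAIDLWAVFRYAPSMTLVAVQNSRRKEEAIDITRLKRNLRYLRCNPKRPT
PAMEQALLKTVPLGMAVITDTVELVEGPGLVSTANYYKAGRFIKKSYLLLLAWLNALNIIEWRTKVAIDK
EGEDFGKFVCFGGLADPYLKSIERNAADAR
>T7
MDRRRSFQLGSKAEYFRLDGAAQYDVAYEKLKHTNLLEQIFLCRNMPRKLIESQVLKGSLPKNGPEAEIS
LGDATPSIECAVQLFTGEFHRLNFEIVNTVEILTYNLEQGGINFEIQPFWTLAPDFKPTPHRLARIAYIY
LNAWSSQGFHQIAKTLANKQAKGELKDSQLTETLKETKKKGLTKAVPSGTVTGFDAFKTGDTENACLSER
STEVHLEWDLPTGSQEREQSFPKALVADDTPSEHFDPTPVEFFRRWSFLPKELTVEYEEAVVMESLLRRF
ETLACYSVDSRASFPWDAVIQMHTPKTSELKEIHDLAFRAAMEIFAEGKSPGVDEQVVGFGSESTILETE
IEDMKLMKFQSLLFEAGAMHFLLEYRLAFCRQMAGDQLKLPHVLYKSLAYACGLEGVAELEESRAQILSR
DRLRKVTNIIRICRLYRIGLLLRLQQELSKGLTLRALYSNYAERDEDAEQEKTLEFPRLIHGAREDGVAH
FEMIHSYGQAPRNCKLDAAQMEQFLGICKSLPLYMIHLDPPNEDTALPFTPPTAMQMVLLLMSVLKLELI
RRGDETVDIACTALGPSKIKAVKMNQQ
>N4
MKLLSETADAAFGRNAYVEASVEGVYGLGFAINTGIGRMRGWELKGWQIAEFGHVESGFLAGNTLSERCG
NRSTFPAGYDLKWAMRNLPVLQHGGDMLADGLSMKCMESSANKWTHPDVEILTGGEVNQCAGKCARNGGT
LNSTALDIGCQAGVNEAQGEDQVWLFAGWDVFGEKLAEVFAVPVEETTMRSALWSLAKVNVMMEFSLRSG
RRLMFSVFWDVLHQRQGFIGPVWAPPPPQMVFRDRENYQLRNVKEAVVYAYVARPILGRWTAQIPLNTLC
YIMVKPGPRETSSLATNIYGKATEVVTMDALRDEKLNAKSMTDAGKQDEKEILVVGRDLALVDGYARVAV
ENVQLIMLRLVSLYEVKKILMGTPEGASGREQQDVGDWGWYAPSLYPNVGAITEWPLYAGDAKRSIVGCQ
IDPRAIESEDDFGAYKGCTTANGMGGEVEAFVGLKLAISIRPIETSILIKFNSTRSSLLPEDLRNVFSPH
NFELLEQTPPELGLGIAKDLYGGGLKVETIANFLSAAAWLKLFKDNTQIIATTYARKVDQIRALPLDVVA

>Mu
MGHAAIENSIRYDFLNRTHQMNFATLGILDVDFLALIPNPSAVVEIGYIVFDACHCFYDEEPNYFSHLIV
APFVAKHPKQFKKYDSKSFTDQERDLLYQVHGEVPFSGSDGEHTLGNKYRGSAPMYSAATPPKPDSGEAA
SAYWAERGSYSAALVRDEREVKQEVEYVIPLVFLGLRRSDGVHIKTKFSAQFPLHGIQRAKQKVSSGSRI
ALLYIAPASTIAVGEDRSKAGNQAGEMPDIRFELVETLKKDEAAVFESDLQDVNSIAFTSDLRYHTEDTE
SSFCFAGDPGNLDQQETAYPVTAFIEAPGLGFVAKKEGTASETDTKPELYVQVDTQCVSLPPGWLITEDS
TQRPRKAHSNYFKPQLILAGIYNDRLKVLMCFELFSAIILGVGKGDALQLKFDGDTGQYDLIKGIIKEVL
GLDDPLSQLQGNAPLAGVNYMVDSNITAWMSESTYFIPHGSYSERTTLLRPVFHLLQGMAEPVDKRVGEG
TFYDRFWHRGDPFLVLITNKEEATHEARYITLSTVAGSPIPEQYNVQRPADVSAGPLDTFYDEATQWAAF
QRGSTRLPGILGAAILFPAYEPAPSEDREPWPKRFQLKDKESGTT
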