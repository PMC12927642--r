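>ref_3.7.1.1_1 synthetic reference
AVTFRVIKTLVLDKVNQSTAQYTVRVGDRKVAFLMVVWNVNFVNVPTRDTLIDIFSFERC
PEQMFIPFRWARFKRMKDNTYGPRSLRYPYGEAGDDGSNKVFKVRCAGKYKQNEGAMRIG
SIFYLQAVVFGKCGALYQAQYVFSFTKAAKVLEYSRLQELQRVGVETAADIKVVYLICVR
AQLAIARDVVMIT
>ref_1.2.3.5_1 synthetic reference
YPEMRSVMFYVYSVKFVQPKISELFAPENNRDDTEAGSWGEVLLLDIDALFRPCASYGNF
VNITVERPKVVHEKGKASDEDNIGGQPYAGEHAYLNEYEVVGKHIGEYPQYRLHEVPTGI
KLPRFGYGSFGALSQLIFQRRTDGPYTEDQTERQGLNWHDAARDKKVIDVKACVLSTQWD
LGDKMLKQFFKVLMDWATGKSGNVYYVLEPTAFKLIREVRKIAYKSSALMTGQPQLHSFL
AANDSIVIFPGVFPEHMFMEQLISLL
>ref_2.8.3.2_1 synthetic reference
IKHPVMLSASYWRDTNLYMAAALHTKGATNPGRYFSRNGVKFALPVLGLGLSKGAIRTGG
LLNVMFRQFGGRRPSNCSVLSPDLMSIKTQVLESLAAHNKKASIPAEFGAAKVLHNTYME
LQWATIAYVVIAGHSEGLIVIHKYGALQSPIAPLLANTPAPACRNDAEEKNKVKAQYIKQ
FYYSPEIIHVADTGDEVTERQDFAVLQLASDGNSYHNVKKVGVALSAFFIQAIGKPLAVA
HQYGIKESHKEEAFEKLEKDTFETFPVANETMTKLYGAKAE
>ref_2.8.3.19_1 synthetic reference
PLTNERVSSAIGGLAKLPKPGVTPNFQDMFDNIKAGPDRRSTGDQETESVNFAKPSEGRR
RRQCSIGNRQDSNRQSSVNRDILTAEHVKSPRQYGGMSIIGSSAFADSPVLNAIWAVETK
LLNKVGDPIGLGGQNQQVLSDNPPDAGLSKENTSLAEAGLQLGAVRKDSRTAAQKPTVVE
NLLWRIVVSATERDINPAMDQADIAGALLGLVLRSE
>ref_4.1.1.8_1 synthetic reference
PAISVLIPEDIKFRKVEYCYALRHLERGDEKRFVEQCRARMGRMCLLGNLGDKLLGGFDE
GHTNHGGGLGGADTRYIAMRTNLCDDGREIESYLYVMQREALISSITGEDSILFALALEF
VSLNPLCNLGGFRNLKLYGRHSHGQLDEGKSAYRIASAELELLSPPITAKTRLKLVFKLL
VPAEDIEIADDEGKLNEKGRYESPVEE
>ref_4.1.1.8_2 synthetic reference
DLTQFPIEDSTCIFGDTAAQSVLLPFVIHSQGLTIQKKEVLSRFARPKDGKPTIQAIGAA
RGVMDHSFNSGRDKEQLKRKPTLRVCGTQQACVLAFNEDEKQFQMKTGVTSAQLNNQDRA
DMPQIRLLVREYREKHVQESGRPHEFAGGVVLSPIPYFTNDIGMSILVLRNNKLKLLERM
GPRRKRELERSVATANLQAAVTTLRRIYTLRYFMFQQIQQSAAKILRDPLFKA
>ref_2.8.3.16_1 synthetic reference
IECPRFQRFAIRGDNSTLVGKQYDIASHAIGTCKYIKGEFSLLVDTLEGASSQKLAIHGA
ETTVQEPGEKARLNSRAEGSPTVNDRDIPLEDTTIFLFDERTIFNTTGRGGKPCLIMILS
AAAANLGKLKRETLGARSELVGWTQLSIFHIHPEKIPTNGAFFMSRLPPGVYYVGYFKPV
NAKKGQ
>ref_7.1.1.1_1 synthetic reference
QIVIMKVFIYYKETAGDWEVLVGSFFKIKGGDLLHEGVPRARIKKIEVLEVGAISGSRED
GYAFRRQLNFHDSDAIAKRGLYSKFTELKVEMQVFCSRDWYSILDQLQGEGLVKALRKGY
IRARLKISLGSTVQVVFKMLSLDLSQDNIKHGDHEMKVQYDIRNCLIPHKGAEELDKEMP
MMASLRFIFALRARIVESTVAEGDFSNSDYRAGGVYFKELNF
>ref_1.2.1.17_1 synthetic reference
HGLDMDQAGLEMNPTISKTRYVNAYAVSSCGPVPATPLKTEEQDVTLAQSAKFRAKTPLF
VYMCDRWLQYAGEIHVEQNALQLAGQREEKRANAVAQLFKQRHLVAKEVNLARVKRIQKG
GDDIRAMASESKETPTPVTSYNVTAVSNWRNSPRKGELLHLRKDETTAAEKDAYRSLYDD
RASQCDVGAHSKYLKLAEIYLEKTRFAREYGFSLATFADNIMPHGAEEVIHVPRAETC
>ref_2.1.2.1_1 synthetic reference
KLYLTHFTWRITYEQSLHEPPLGEDGVVDQLEIYLGLGLYRIGWMARKDQKVNDEKGLAK
IERRATPAKKLQMIVYLLAKNEPNWQVVDVVHKFQNNEAQSILIKVFTASAFKDAADTGI
SIKDATSDDEVLDDTVIATDIASEFRHLTQTGKNYLDTDVQLYVKFAFATKLPNHMIVYY
VISLNCNANAVEDIGSGVLASLADGC
>ref_2.6.1.45_1 synthetic reference
VPSNKAFFAQNPELPRFAIQEDGRNGRTLATLGESRWVKPFSVPARASFTAALHRLDAGW
GKLRGDNTNRELVHPWLEEEIITENLPAMINEFNEDGDMQSAVTKTGAPEYSSLTRDSNG
TMLFAEDKRARLGAVELAFADLLVGQIDQRPGHSYLLKYMLPPRRERDPIGGLPDVTLVH
KINKQPRSFETIEDKDIFF
>ref_4.1.1.47_1 synthetic reference
LVQKVDFLCAPRVTVGEKNPLPAGVTALKPVLLLEYGVCAPEYDPRSYSDERAKELKLEA
VLGQIKPQEEECVKHVIEGLSTEIKRALVTKAPSAFQDSKVKSTKMQTQFVNYGHLSSSS
EQSSLLVDETLNLTTEKTNRIPAIHFQAKSSGFLSLACLTPVATAFIVLPRLMEFPIGIK
DFNENADSPSAISGKVMYTSGRNDHKNLEIGAWIWVQPVSSKIVYELLGELWKPKQITAD
MDTGLQLKLQISRVNEA
>ref_4.1.1.47_2 synthetic reference
KIGKEGETDAHAVTITREVRFAEFTIAIFICLPAGSRTVVPMAHGLRAGTQNVAISIIMQ
MQGSRDGPDLFEIEQLQQSALFDIEHAPVVQYDRAVHESENYLEQMTVNAQHVIIFEPIS
PEPVGEVDQKSWSQLISQAAKRLPLLPLFYLMLFALGYVAYKLKSLFGFLYCREIRCADE
KSM
>ref_1.1.1.60_1 synthetic reference
LRMVVYLYATDDTVTDSPEGPEGKLSNIYDQVDLNILPYARQLPTKAKSFNIIETIIKPA
ASGAWERAIALDLQERNLLISQVGKDVLTFPFILLQRQFIPLAACSRILAILIVLKMKFR
PMKANQHGRCNKHLTDDARSDEASGNGLSLFCETGEKRISYETILPHRNTLDKGMQMFQA
KNHETFPVQAIELIKIKIRPGTADPKEEVMYCVYENGRSKVRPLILTLQAIIHTDNDDQS
GIKQRAATRYMVYMKEDP
>ref_2.7.1.31_1 synthetic reference
PGGSAKIYAAYKDYCEGMSLFIFNTESYSMKQRKLDPQFSKVAGGPGHKYSDSAIKRYGG
NCGTTVLETYEVSSDLLIKSLYLCIWCGEETTLAKLIVDLKPPGVVEDICLKKQVRPTQE
AGATADTGNHNSTASVSIITVPVHYMVAILFVHDGANDSRKDAQDTIHCFDSIQLRANIQ
ESVLENQSNTFNNNNDNFEKGLIELSRDHLLLRTEGRSGD
>ref_1.1.1.29_1 synthetic reference
VYGGVIATELPSKQTVFKEMKARIKPFQINVAQKVTGLKIEIHLFAEYVNQRKSPEPYAR
DDQGTPQKGRGAYDGMHLAVEKPVHDAFCTLDSHHTVPYLKLQPDEQDNAEAMLKYNPDG
DNIRIGGAIILEPEAVIVSILVLTSSKKVYEKLTYIISLSASYILEEEIRNAAQILLQVP
DVPGQSTRIHELVKGGFTAYTDDHVKNLVRWKKDYMLVRAPVANIEWGDRELYP
>ref_4.1.1.2_1 synthetic reference
RADRVELVYYYERTFHHNEPRFIDYSKDGIFPSLMSYGRKPTFQSGISTREKQTDAKASN
LPAAVRRCTACIVEEAGCTEQAASKETDVTPPMIERLYQSAGGQQQAANLPSVVEGFSDE
KLSRFGWRDQNPNKFDSYIRTVQAGPAVDYGLMMTDAFGAGWAFIEGVANAPSVVERRVR
VYLRGIINFDYIAPGSFDQPPSQ
>ref_1.2.3.4_1 synthetic reference
HEALPSVAGVARKLQGNASVTGIKRTRYSSYENAPESSDKATFLSLDFKGADVSWEQINA
AKLLSGEDYIVDIDFARNGGFMVNHAVFEAIVPMQRPRMVKGMYKEVSQCDSSNKAFKDE
GIITSAEGIMLVHEAQIVTERRSKKKFRTGRKAAIVLEEEAITWKPLPILRCLSDLVVVY
GELGEVLDTLKRKITQLHTFGTTDWCEGVELVHTNCKTVVAPLLMPFKLPNFTSTPDHLM
ETQGPGRARRSTNVGKSLDWVRCEDISDAAKELPKPEKFIACWVTQIQPSRSFVAAA
>ref_4.1.1.20_1 synthetic reference
TMIARSEDRVIECIDTVFCLKRGKYQYTLMQNSGDLGFIRFAAALGQAGNEDNEHLGCQV
TRSARRGDRVGYKDAGDSIFAPYRCTARAHVDRFFVTALVNKAILQSRERGDSGIEDEDE
ILFHDGPFAKLTFSWTPAEHLKATFHSCSVVAYNYKPTHMNWGTHSLETDMLGSQVKPDN
IELLTKGGPDNAKQTGLQFYLVLFLGSACQRKPIGTGFNGSITGSQKSTSQAGVTPFSGA
AMMYPNGRLVIGFHIAK
>ref_OxlT_1 synthetic reference
KALRVRADFESAIILFGFVVHSYTINKIIRSVSKQANLQCSRLLHIAVQANGGYEAEPND
LTKNENGGFDAHVPKGDSARLVAYSELFQFRAPGQSWGTTGVTREVVEFNRATYGEEIDW
YVLVMFPPVMTISSSSIEKDQGSDDNVISCGTLIDKLLDKAVYWINFCILVIEYQEQRDS
EIVVDLPDHKEFLGVLGFILGGGNVKVHALGSVIAVIKDINLSKAHAATCVEVMSDAARA
GMYGTEYRVTTEVKAG
>ref_6.2.1.8_1 synthetic reference
CIPEIGDEVIDTNFGEKRNLMGLSVADKLELLNLFAQNQQGNSMIGELSIKEDELLGDSI
YLDTYNKVFQQEILTSRLMGGIAARVCSKEGEGEIRLQNKYTELIISLMKGYIETGINKY
VDSREREKKAKVNTKLPTPTEYCMSRSQNASVVFHDRQERLTAGGLAILGDVPVLIEPVV
RTYETGNIDSPAVGSSDVMKTVYEASGRISNDPKSEMELFEDAPIVSKRNFELFVLHLLS
EGATVLYYQGFSALELTEEMTLTLFNFHEGGRKGKEGTWKGLLFVENESLRVPQEG
>ref_1.1.1.26_1 synthetic reference
NVIFCPYASFAGQARGEEFSENVSNGDDTALTVAADAFDRIPAHVDGSRQVVSPEECLKD
KSDDFVKELSSAWREESDRAPSITQEDRPEVARITANNARKSDNMISPSPSAHSKLGTPP
SDVDVVVTTDVERTDLEGKIIYALVRDVSAKVGGIQHEADRAHYPQFITDGDRKLAQQTC
PTYLGWSTPEIPLANNADMSAKCSDSGVTSSTESVEIRSCGRAVSVKVQGGLLNTLAKGR
PSTVQDQSHPLTNDHKAAYQTDISVGCLRPTQTEDPRTFTGQ
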