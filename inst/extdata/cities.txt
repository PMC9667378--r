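Paris
Lyon
Marseille
Toulouse
Nice
Nantes
Strasbourg
Montpellier
Bordeaux
Lille
Rennes
Reims
Le Havre
Saint-Étienne
Toulon
Grenoble
Dijon
Angers
Nîmes
Villeurbanne
Clermont-Ferrand
Le Mans
Aix-en-Provence
Brest
Tours
Amiens
Limoges
Annecy
Perpignan
Boulogne-Billancourt
Metz
Besançon
Orléans
Saint-Denis
Argenteuil
Rouen
Montreuil
Mulhouse
Caen
Nancy
Saint-Paul
Tourcoing
Roubaix
Nanterre
Vitry-sur-Seine
Avignon
Créteil
Poitiers
Dunkerque
Aubervilliers
Versailles
Aulnay-sous-Bois
Asnières-sur-Seine
Colombes
Saint-Pierre
Courbevoie
Fort-de-France
Cherbourg-en-Cotentin
Rueil-Malmaison
Champigny-sur-Marne
Béziers
La Rochelle
Pau
Saint-Maur-des-Fossés
Cannes
Antibes
Drancy
Ajaccio
Mérignac
Saint-Nazaire
Colmar
Issy-les-Moulineaux
Noisy-le-Grand
Évry-Courcouronnes
Vénissieux
Cergy
Bourges
La Seyne-sur-Mer
Levallois-Perret
Quimper
Valence
Villeneuve-d'Ascq
Antony
Pessac
Troyes
Montauban
Chambéry
Niort
Neuilly-sur-Seine
Sarcelles
Le Blanc-Mesnil
Lorient
Beauvais
Hyères
Épinay-sur-Seine
Meaux
Chelles
Villejuif
Narbonne
La Roche-sur-Yon
Saint-Quentin
Bayonne
Cholet
Vannes
Clichy
Bondy
Fréjus
Saint-Louis
Sevran
Arles
Saint-Herblain
Laval
Maisons-Alfort
Angoulême
Boulogne-sur-Mer
Évreux
Wattrelos
Saint-Brieuc
Arras
Compiègne
Grasse
Montrouge
Gennevilliers
Saint-Malo
Blois
Rosny-sous-Bois
Albi
Châlons-en-Champagne
Saint-Germain-en-Laye
Tarbes
Alfortville
Sète
Chartres
Salon-de-Provence
Saint-Ouen-sur-Seine
Puteaux
Bastia
Valenciennes
Brive-la-Gaillarde
Gagny
Châteauroux
Belfort
Thionville
Charleville-Mézières
Le Cannet
Saint-Martin-sur-Ocre
Sainte-Anne-d'Auray
Saint-Priest
Bron
Montluçon
Châtillon
Vaulx-en-Velin
Saint-André
Carcassonne
Rezé
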